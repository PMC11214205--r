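#' Fit a pedigree animal model by AI-REML
#'
#' Restricted maximum likelihood for the mixed model
#' `y = X b + u_a + u_c + e`, where `u_a` is the additive genetic (animal)
#' effect with covariance `sigma2_a * A` (A the pedigree numerator
#' relationship matrix), `u_c` a common-litter effect with covariance
#' `sigma2_c * I`, and `e` the residual. Estimation uses average-information
#' (AI) updates with step halving and an expectation-maximization fallback;
#' standard errors come from the inverse average-information matrix.
#'
#' A two-trait model is requested with a matrix response,
#' `cbind(y1, y2) ~ ...`; all three covariance structures are then full 2x2
#' matrices and the genetic correlation `rG` is reported with a delta-method
#' standard error.
#'
#' @param formula model formula; left side a trait (or `cbind()` of two),
#'   right side the fixed effects (e.g. `~ sex + batch`).
#' @param data data.frame with the response, fixed covariates, the animal id
#'   column and (optionally) the litter column.
#' @param ped a [pedigree()] covering all animals in `data` (ancestors
#'   included).
#' @param id name of the animal-id column in `data`.
#' @param litter name of the common-litter column, or `NULL` to omit the
#'   litter effect.
#' @param start optional named list with elements `a`, `c`, `e` giving
#'   starting covariance matrices (scalars for one trait).
#' @param maxit maximum REML iterations (error past this, per the declared
#'   contract).
#' @param tol_logl,tol_par convergence tolerances on the log-likelihood
#'   change and the relative parameter change.
#' @param verbose print the iteration trace.
#' @return An object of class `"animal_reml"`; see [summary.animal_reml()].
#'   Key elements: `varcomp` (list of covariance matrices `a`, `c`, `e`),
#'   `h2`, `c2` (per-trait ratios with SEs), `rG` (two-trait fits),
#'   `beta` (fixed effects), `logLik`, `converged`, `boundary`.
#' @export
animal_reml <- function(formula, data, ped, id = "animal", litter = "litter",
                        start = NULL, maxit = 200, tol_logl = 1e-8,
                        tol_par = 1e-6, verbose = FALSE) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1, dimnames = list(NULL, deparse(formula[[2]])))
  tt <- ncol(y)
  if (tt > 2) stop("at most two traits are supported")
  keep <- match(rownames(mf), rownames(data))
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased: ", paste(aliased, collapse = ", "))
  }
  ids <- as.character(data[[id]][keep])
  if (anyDuplicated(ids)) stop("one record per animal is required")
  Ma <- a_matrix(ped, subjects = ids)
  n <- length(ids)
  structures <- list(a = Ma)
  qlev <- c(a = n)
  if (!is.null(litter)) {
    lit <- factor(data[[litter]][keep])
    if (nlevels(lit) < 2) stop("need at least 2 litters for a litter effect")
    Zc <- stats::model.matrix(~ 0 + lit)
    structures$c <- tcrossprod(Zc)
    qlev <- c(qlev, c = nlevels(lit))
  }
  structures$e <- diag(n)
  qlev <- c(qlev, e = n)

  fit <- reml_engine(y, X, structures, qlev, start = start, maxit = maxit,
                     tol_logl = tol_logl, tol_par = tol_par, verbose = verbose)
  fit$call <- match.call()
  fit$traits <- colnames(y)
  fit$n <- n
  fit$ids <- ids
  class(fit) <- "animal_reml"
  fit
}

# Core dense AI-REML over V = sum_g Sigma_g (x) M_g (trait-major stacking).
# y: n x t, X: n x p, structures: named list of n x n symmetric matrices,
# qlev: number of levels per structure (EM fallback scaling).
reml_engine <- function(y, X, structures, qlev, start = NULL, maxit = 200,
                        tol_logl = 1e-8, tol_par = 1e-6, verbose = FALSE) {
  n <- nrow(y); tt <- ncol(y); G <- length(structures)
  gn <- names(structures)
  npar_g <- tt * (tt + 1) / 2
  # parameter layout: per structure, vech upper triangle (11, 12, 22)
  pairs <- if (tt == 1) matrix(1, 1, 2) else rbind(c(1, 1), c(1, 2), c(2, 2))
  theta_to_mats <- function(theta) {
    lapply(seq_len(G), function(g) {
      v <- theta[(g - 1) * npar_g + seq_len(npar_g)]
      S <- matrix(0, tt, tt)
      for (k in seq_len(npar_g)) S[pairs[k, 1], pairs[k, 2]] <- S[pairs[k, 2], pairs[k, 1]] <- v[k]
      S
    })
  }
  mats_to_theta <- function(mats) {
    unlist(lapply(mats, function(S) S[cbind(pairs[, 1], pairs[, 2])]))
  }

  # residual phenotypic covariance after the fixed effects, for starting values
  res0 <- stats::lm.fit(X, y)$residuals
  if (is.null(dim(res0))) res0 <- matrix(res0, ncol = 1)
  Rp <- crossprod(res0) / (n - ncol(X))
  if (is.null(start)) {
    share <- stats::setNames(rep(0.5 / max(G - 1, 1), G), gn)
    share["e"] <- 0.5
    mats0 <- lapply(gn, function(g) share[[g]] * Rp)
  } else {
    mats0 <- lapply(gn, function(g) {
      S <- start[[g]]
      if (is.null(S)) stop("start lacks component ", g)
      if (length(S) == 1 && tt == 1) S <- matrix(S, 1, 1)
      as.matrix(S)
    })
  }
  theta <- mats_to_theta(mats0)
  ystar <- as.numeric(y)  # trait-major
  Xstar <- if (tt == 1) X else {
    XX <- rbind(cbind(X, 0 * X), cbind(0 * X, X))
    colnames(XX) <- paste(rep(colnames(y), each = ncol(X)), colnames(X), sep = ":")
    XX
  }
  p <- ncol(Xstar)
  floor_var <- 1e-10

  project <- function(theta) {
    mats <- theta_to_mats(theta)
    mats <- lapply(mats, function(S) {
      diag(S) <- pmax(diag(S), floor_var)
      if (tt == 2) {
        r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
        if (!is.finite(r)) S[1, 2] <- S[2, 1] <- 0
        else if (abs(r) > 0.999) S[1, 2] <- S[2, 1] <- sign(r) * 0.999 * sqrt(S[1, 1] * S[2, 2])
      }
      S
    })
    mats_to_theta(mats)
  }
  build_V <- function(theta) {
    mats <- theta_to_mats(theta)
    V <- matrix(0, n * tt, n * tt)
    for (g in seq_len(G)) {
      S <- mats[[g]]; M <- structures[[g]]
      for (r in seq_len(tt)) for (s in seq_len(tt)) {
        if (S[r, s] != 0) {
          ir <- (r - 1) * n + seq_len(n); is <- (s - 1) * n + seq_len(n)
          V[ir, is] <- V[ir, is] + S[r, s] * M
        }
      }
    }
    V
  }
  loglik_only <- function(theta) {
    V <- build_V(theta)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    ldV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, backsolve(ch, ystar, transpose = TRUE))
    Vi_X <- backsolve(ch, backsolve(ch, Xstar, transpose = TRUE))
    XtViX <- crossprod(Xstar, Vi_X)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(-Inf)
    ldX <- 2 * sum(log(diag(chx)))
    beta <- backsolve(chx, backsolve(chx, crossprod(Vi_X, ystar), transpose = TRUE))
    Py <- Vi_y - Vi_X %*% beta
    -0.5 * (ldV + ldX + sum(ystar * Py))
  }

  trace_hist <- numeric(0)
  ll <- -Inf
  iter_info <- NULL
  stall <- 0L
  for (iter in seq_len(maxit)) {
    V <- build_V(theta)
    ch <- chol(V)
    W <- chol2inv(ch)                       # V^{-1}
    ldV <- 2 * sum(log(diag(ch)))
    WX <- W %*% Xstar
    XtViX <- crossprod(Xstar, WX)
    chx <- chol(XtViX)
    ldX <- 2 * sum(log(diag(chx)))
    XtViX_inv <- chol2inv(chx)
    beta <- XtViX_inv %*% crossprod(WX, ystar)
    w <- W %*% ystar - WX %*% beta          # P y
    ll_new <- -0.5 * (ldV + ldX + sum(ystar * w))
    P <- W - WX %*% XtViX_inv %*% t(WX)

    # scores and AI over all parameters
    m <- G * npar_g
    score <- numeric(m)
    Umat <- matrix(0, n * tt, m)
    wblk <- matrix(w, n, tt)
    for (g in seq_len(G)) {
      M <- structures[[g]]
      Mw <- M %*% wblk                       # n x t
      for (k in seq_len(npar_g)) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        pi_ <- (i - 1) * n + seq_len(n); pj <- (j - 1) * n + seq_len(n)
        if (i == j) {
          trPM <- sum(P[pi_, pi_] * M)
          quad <- sum(wblk[, i] * Mw[, i])
          v <- numeric(n * tt); v[pi_] <- Mw[, i]
        } else {
          trPM <- 2 * sum(P[pi_, pj] * M)
          quad <- 2 * sum(wblk[, i] * Mw[, j])
          v <- numeric(n * tt); v[pi_] <- Mw[, j]; v[pj] <- Mw[, i]
        }
        idx <- (g - 1) * npar_g + k
        score[idx] <- -0.5 * (trPM - quad)
        Umat[, idx] <- v
      }
    }
    PU <- W %*% Umat - WX %*% (XtViX_inv %*% crossprod(WX, Umat))
    AI <- 0.5 * crossprod(Umat, PU)

    conv_ll <- is.finite(ll) && abs(ll_new - ll) < tol_logl
    ll <- ll_new
    trace_hist <- c(trace_hist, ll)
    if (verbose) cat(sprintf("it %2d  logL %.8f  theta %s\n", iter, ll,
                             paste(signif(theta, 4), collapse = " ")))

    # Active set: parameters pinned at a boundary with the score pushing
    # outward are frozen, so the AI step retains curvature information only
    # for the free directions.
    is_diag <- pairs[rep(seq_len(npar_g), G), 1] == pairs[rep(seq_len(npar_g), G), 2]
    active <- rep(FALSE, m)
    mats_now <- theta_to_mats(theta)
    for (g in seq_len(G)) for (k in seq_len(npar_g)) {
      idx <- (g - 1) * npar_g + k
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (i == j) {
        if (theta[idx] <= floor_var * 1.01 && score[idx] < 0) active[idx] <- TRUE
      } else {
        S <- mats_now[[g]]
        r <- S[i, j] / sqrt(S[i, i] * S[j, j])
        if (is.finite(r) && abs(r) >= 0.9985 && sign(score[idx]) == sign(r)) active[idx] <- TRUE
      }
    }
    free <- which(!active)

    # Marquardt-damped AI step on the free parameters; EM-style fallback if
    # no damping level helps
    step_ok <- FALSE
    best_ll <- ll; best_cand <- NULL
    if (length(free)) {
      AIf <- AI[free, free, drop = FALSE]
      ridge <- diag(diag(AIf), nrow = length(free)) +
        mean(abs(diag(AIf))) * 1e-8 * diag(length(free))
      scale_ref <- mean(abs(theta[is_diag]))
      for (lam in c(0, 1e-4, 1e-2, 1, 1e2, 1e4, 1e6)) {
        df <- tryCatch(solve(AIf + lam * ridge, score[free]), error = function(e) NULL)
        if (is.null(df)) next
        delta <- numeric(m); delta[free] <- df
        # trust cap: a variance may shrink by at most 75% or grow by at most
        # 3x (+ a small absolute allowance) in one step
        s <- 1
        for (kk in which(is_diag & delta != 0)) {
          lim <- if (delta[kk] < 0) 0.75 * theta[kk] else 3 * theta[kk] + 0.1 * scale_ref
          s <- min(s, lim / abs(delta[kk]))
        }
        delta <- s * delta
        cand_try <- project(theta + delta)
        ll_c <- loglik_only(cand_try)
        if (is.finite(ll_c) && ll_c > best_ll) {
          # first damping level that improves the likelihood wins
          best_ll <- ll_c; best_cand <- cand_try
          break
        }
      }
    }
    if (!is.null(best_cand)) { cand <- best_cand; step_ok <- TRUE }
    if (verbose) cat(sprintf("   step: %s  active: %s\n",
                             if (step_ok) "AI" else "EM",
                             paste(which(active), collapse = ",")))
    if (!step_ok) {
      # EM update: Sigma_g <- Sigma_g + Sigma_g (Q_g - T_g) Sigma_g / q_g
      mats <- theta_to_mats(theta)
      for (g in seq_len(G)) {
        Sg <- matrix(0, tt, tt)
        for (k in seq_len(npar_g)) {
          i <- pairs[k, 1]; j <- pairs[k, 2]
          s2 <- 2 * score[(g - 1) * npar_g + k] / (if (i == j) 1 else 2)
          Sg[i, j] <- Sg[j, i] <- s2
        }
        mats[[g]] <- mats[[g]] + (mats[[g]] %*% Sg %*% mats[[g]]) / qlev[g]
      }
      cand <- project(mats_to_theta(mats))
      ll_c <- loglik_only(cand)
      if (!is.finite(ll_c)) cand <- theta  # stay put; convergence test decides
    }
    dpar <- max(abs(cand - theta) / (abs(theta) + 1))
    stall <- if (conv_ll) stall + 1L else 0L
    # a log-likelihood gain below 1e-3 over ten iterations means the fit is
    # crawling along a near-flat ridge; the components there are determined
    # only up to that flatness, so report them with their (large) SEs
    ridge_stall <- iter >= 25 &&
      (trace_hist[iter] - trace_hist[iter - 10]) < 1e-3
    if ((conv_ll && dpar < tol_par) || stall >= 3L || ridge_stall) {
      # keep the parameter vector the reported beta / AI / logLik were
      # evaluated at; three consecutive stalled log-likelihood changes are
      # treated as convergence on a constraint boundary
      iter_info <- list(iterations = iter, converged = TRUE)
      break
    }
    theta <- cand
    if (iter == maxit) {
      stop("AI-REML did not converge in ", maxit, " iterations; logL trace: ",
           paste(signif(utils::tail(trace_hist, 8), 8), collapse = ", "))
    }
  }

  mats <- theta_to_mats(theta)
  names(mats) <- gn
  vcov_theta <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  se_theta <- sqrt(pmax(diag(vcov_theta), 0))
  boundary <- any(vapply(mats, function(S) any(diag(S) <= floor_var * 1.01), logical(1)))

  # variance ratios per trait with delta-method SEs
  ratios <- ratio_table(mats, vcov_theta, gn, tt, pairs, npar_g)
  out <- list(varcomp = mats, se_theta = se_theta, vcov_theta = vcov_theta,
              theta = theta, structure_names = gn,
              h2 = ratios$h2, c2 = ratios$c2, rG = ratios$rG,
              beta = stats::setNames(as.numeric(beta), colnames(Xstar)),
              beta_vcov = XtViX_inv,
              logLik = ll, trace = trace_hist,
              iterations = iter_info$iterations, converged = isTRUE(iter_info$converged),
              boundary = boundary)
  out
}

# h2 = sigma2_a / sum, c2 = sigma2_c / sum per trait; rG for two traits.
ratio_table <- function(mats, vcov_theta, gn, tt, pairs, npar_g) {
  G <- length(mats)
  diag_idx <- function(g, trait) {
    k <- which(pairs[, 1] == trait & pairs[, 2] == trait)
    (g - 1) * npar_g + k
  }
  h2 <- c2 <- matrix(NA_real_, tt, 2, dimnames = list(NULL, c("estimate", "se")))
  for (trait in seq_len(tt)) {
    vars <- vapply(seq_len(G), function(g) mats[[g]][trait, trait], numeric(1))
    total <- sum(vars)
    idx <- vapply(seq_len(G), function(g) diag_idx(g, trait), numeric(1))
    for (comp in c("a", "c")) {
      gpos <- match(comp, gn)
      if (is.na(gpos)) next
      ratio <- vars[gpos] / total
      grad <- -vars[gpos] / total^2 + (seq_len(G) == gpos) / total
      se <- sqrt(max(0, t(grad) %*% vcov_theta[idx, idx] %*% grad))
      if (comp == "a") h2[trait, ] <- c(ratio, se) else c2[trait, ] <- c(ratio, se)
    }
  }
  rG <- NULL
  if (tt == 2) {
    Sa <- mats[[match("a", gn)]]
    r <- Sa[1, 2] / sqrt(Sa[1, 1] * Sa[2, 2])
    flag <- abs(r) > 1
    r <- max(min(r, 1), -1)
    g <- match("a", gn)
    idx <- (g - 1) * npar_g + 1:3     # (11, 12, 22)
    grad <- c(-r / (2 * Sa[1, 1]), 1 / sqrt(Sa[1, 1] * Sa[2, 2]), -r / (2 * Sa[2, 2]))
    se <- sqrt(max(0, t(grad) %*% vcov_theta[idx, idx] %*% grad))
    cov_idx <- idx[2]
    rG <- list(estimate = r, se = se, cov_a = Sa[1, 2], clipped = flag)
  }
  list(h2 = h2, c2 = c2, rG = rG)
}

#' @export
print.animal_reml <- function(x, ...) {
  tt <- length(x$traits)
  cat("Animal-model REML fit (", if (tt == 1) "one trait" else "two traits", ")\n", sep = "")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  n =", x$n, " logLik =", format(x$logLik, digits = 8),
      " iterations =", x$iterations, "\n")
  for (g in x$structure_names) {
    lab <- c(a = "additive", c = "litter", e = "residual")[g]
    S <- x$varcomp[[g]]
    cat(sprintf("  sigma2_%s (%s): %s\n", g, lab,
                paste(signif(S[upper.tri(S, diag = TRUE)], 4), collapse = " ")))
  }
  for (trait in seq_len(tt)) {
    cat(sprintf("  %s: h2 = %.3f (%.3f)", x$traits[trait],
                x$h2[trait, 1], x$h2[trait, 2]))
    if (!all(is.na(x$c2[trait, ]))) cat(sprintf("  c2 = %.3f (%.3f)", x$c2[trait, 1], x$c2[trait, 2]))
    cat("\n")
  }
  if (!is.null(x$rG)) cat(sprintf("  rG = %.3f (%.3f)\n", x$rG$estimate, x$rG$se))
  if (x$boundary) cat("  note: estimate at the variance boundary\n")
  invisible(x)
}

#' @export
summary.animal_reml <- function(object, ...) {
  object
}

#' @export
coef.animal_reml <- function(object, ...) object$beta

#' @export
logLik.animal_reml <- function(object, ...) {
  structure(object$logLik, df = length(object$theta), class = "logLik")
}

#' @export
vcov.animal_reml <- function(object, ...) object$vcov_theta

#' Extract heritability / genetic correlation from an animal-model fit
#'
#' @param object an `animal_reml` fit.
#' @return `heritability()`: per-trait data.frame of h2 and c2 with SEs;
#'   `genetic_correlation()`: list with `estimate` and `se` (two-trait fits).
#' @export
heritability <- function(object) {
  stopifnot(inherits(object, "animal_reml"))
  data.frame(trait = object$traits,
             h2 = object$h2[, 1], h2_se = object$h2[, 2],
             c2 = object$c2[, 1], c2_se = object$c2[, 2],
             row.names = NULL)
}

#' @rdname heritability
#' @export
genetic_correlation <- function(object) {
  stopifnot(inherits(object, "animal_reml"))
  if (is.null(object$rG)) stop("genetic correlation requires a two-trait fit")
  object$rG
}

#' Observed-scale heritability of the binary enterotype trait
#'
#' Fits the linear animal model directly to the 0/1 enterotype indicator
#' (the observed scale), and reports alongside the Dempster-Lerner conversion
#' to the liability scale, `h2_liab = h2_obs * p(1-p) / z^2` with `p` the
#' prevalence and `z` the standard-normal density at its quantile.
#'
#' @param data data.frame with a 0/1 (or two-level factor) enterotype column
#'   plus fixed covariates, animal id and litter.
#' @param trait name of the enterotype column.
#' @param fixed right-hand-side formula of fixed effects, e.g. `~ sex + batch`.
#' @param ped,id,litter,... passed to [animal_reml()].
#' @return The `animal_reml` fit with an extra `liability` element
#'   (`h2_liab`, `prevalence`).
#' @export
heritability_binary <- function(data, trait, fixed, ped, id = "animal",
                                litter = "litter", ...) {
  y <- data[[trait]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  if (length(unique(stats::na.omit(y))) < 2) stop("binary trait has a single class")
  data$.binary01 <- as.numeric(y)
  f <- stats::reformulate(attr(stats::terms(fixed), "term.labels"), response = ".binary01")
  fit <- animal_reml(f, data, ped, id = id, litter = litter, ...)
  p <- mean(data$.binary01, na.rm = TRUE)
  z <- stats::dnorm(stats::qnorm(p))
  fit$liability <- list(h2_liab = fit$h2[1, 1] * p * (1 - p) / z^2, prevalence = p)
  fit$traits <- trait
  fit
}
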