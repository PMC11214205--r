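# helpers to simulate small animal-model datasets ------------------------

halfsib_data <- function(ns, no, h2, seed, mu = 10) {
  set.seed(seed)
  sires <- paste0("S", seq_len(ns))
  off <- paste0("O", seq_len(ns * no))
  ped <- pedigree(data.frame(animal = c(sires, off),
                             sire = c(rep(NA, ns), rep(sires, each = no)),
                             dam = NA))
  bv_s <- rnorm(ns, 0, sqrt(h2))
  y <- mu + rep(bv_s / 2, each = no) + rnorm(ns * no, 0, sqrt(h2 * 3 / 4 + (1 - h2)))
  list(ped = ped,
       data = data.frame(animal = off, y = y, sirefac = rep(sires, each = no)))
}

# nested full-sib families with litters (two dams per sire)
family_data <- function(ns, h2, c2, seed, rho = NULL, h2b = NULL) {
  set.seed(seed)
  nd <- 2; no <- 4
  sires <- paste0("S", seq_len(ns)); dams <- paste0("D", seq_len(ns * nd))
  off <- paste0("O", seq_len(ns * nd * no))
  ped <- pedigree(data.frame(
    animal = c(sires, dams, off),
    sire = c(rep(NA, ns + ns * nd), rep(rep(sires, each = nd), each = no)),
    dam = c(rep(NA, ns + ns * nd), rep(dams, each = no))))
  A <- a_matrix(ped)
  litter <- rep(paste0("L", seq_len(ns * nd)), each = no)
  n <- length(off)
  rt <- t(chol(A + diag(1e-10, nrow(A))))
  sexf <- sample(c("M", "F"), n, TRUE)
  if (is.null(rho)) {
    u <- as.numeric(rt %*% rnorm(nrow(A))) * sqrt(h2)
    names(u) <- rownames(A)
    lit <- setNames(rnorm(ns * nd, 0, sqrt(c2)), paste0("L", seq_len(ns * nd)))
    y <- 1 + 0.3 * (sexf == "M") + u[off] + lit[litter] +
      rnorm(n, 0, sqrt(1 - h2 - c2))
    data.frame(animal = off, y = y, sex = sexf, litter = litter) -> dat
  } else {
    Sa <- diag(sqrt(c(h2, h2b))) %*% matrix(c(1, rho, rho, 1), 2) %*%
      diag(sqrt(c(h2, h2b)))
    U <- rt %*% matrix(rnorm(2 * nrow(A)), ncol = 2) %*% chol(Sa)
    rownames(U) <- rownames(A)
    lit <- matrix(rnorm(2 * ns * nd, 0, sqrt(c2)), ncol = 2)
    rownames(lit) <- paste0("L", seq_len(ns * nd))
    E <- cbind(rnorm(n, 0, sqrt(1 - h2 - c2)), rnorm(n, 0, sqrt(1 - h2b - c2)))
    Y <- cbind(1, 2) [rep(1, n), ] + U[off, ] + lit[litter, ] + E
    dat <- data.frame(animal = off, y1 = Y[, 1], y2 = Y[, 2], sex = sexf,
                      litter = litter)
  }
  list(ped = ped, data = dat)
}

# independent REML log-likelihood (direct formula, no shared code path)
direct_negll <- function(v, y, X, Ms) {
  V <- Reduce(`+`, Map(`*`, as.list(v), Ms))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi <- chol2inv(ch)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
           (t(r) %*% Vi %*% r)[1])
}

# ------------------------------------------------------------------------

test_that("REML equals the ANOVA sire-model estimator on a balanced half-sib design", {
  hs <- halfsib_data(ns = 100, no = 10, h2 = 0.3, seed = 42)
  fit <- animal_reml(y ~ 1, hs$data, hs$ped, litter = NULL)
  av <- anova(lm(y ~ sirefac, hs$data))
  s2s <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / 10
  h2_anova <- 4 * s2s / (s2s + av$`Mean Sq`[2])
  expect_equal(unname(fit$h2[1, 1]), h2_anova, tolerance = 1e-6)
  expect_true(fit$converged)
  # likelihood trace is monotone non-decreasing
  expect_true(all(diff(fit$trace) > -1e-6))
})

test_that("REML maximises the independently coded restricted likelihood", {
  fd <- family_data(ns = 30, h2 = 0.5, c2 = 0.1, seed = 7)
  fit <- animal_reml(y ~ sex, fd$data, fd$ped)
  off <- fd$data$animal
  A <- a_matrix(fd$ped, subjects = off)
  Mc <- tcrossprod(model.matrix(~ 0 + factor(fd$data$litter)))
  X <- model.matrix(~ sex, fd$data)
  Ms <- list(A, Mc, diag(length(off)))
  o <- optim(c(0.3, 0.2, 0.6), direct_negll, y = fd$data$y, X = X, Ms = Ms,
             method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$logLik, -o$value, tolerance = 1e-4)
  est <- c(fit$varcomp$a[1], fit$varcomp$c[1], fit$varcomp$e[1])
  expect_equal(est, pmax(o$par, 0), tolerance = 0.05)
})

test_that("bivariate REML maximises the independent likelihood", {
  fd <- family_data(ns = 30, h2 = 0.4, c2 = 0.1, seed = 21, rho = 0.6, h2b = 0.35)
  fit <- animal_reml(cbind(y1, y2) ~ sex, fd$data, fd$ped)
  off <- fd$data$animal; n <- length(off)
  A <- a_matrix(fd$ped, subjects = off)
  Mc <- tcrossprod(model.matrix(~ 0 + factor(fd$data$litter)))
  X <- model.matrix(~ sex, fd$data)
  Xs <- rbind(cbind(X, 0 * X), cbind(0 * X, X))
  ys <- c(fd$data$y1, fd$data$y2)
  mkS <- function(p) { L <- matrix(c(p[1], p[2], 0, p[3]), 2); L %*% t(L) }
  negll2 <- function(p) {
    S <- list(mkS(p[1:3]), mkS(p[4:6]), mkS(p[7:9]))
    Ms <- list(A, Mc, diag(n))
    V <- matrix(0, 2 * n, 2 * n)
    for (g in 1:3) for (r in 1:2) for (s in 1:2) {
      V[(r - 1) * n + 1:n, (s - 1) * n + 1:n] <-
        V[(r - 1) * n + 1:n, (s - 1) * n + 1:n] + S[[g]][r, s] * Ms[[g]]
    }
    direct_negll(1, ys, Xs, list(V))
  }
  # polishing from the engine solution must not find a better optimum
  Sa <- fit$varcomp$a; Sc <- fit$varcomp$c; Se <- fit$varcomp$e
  tochol <- function(S) { L <- t(chol(S + diag(1e-8, 2))); c(L[1, 1], L[2, 1], L[2, 2]) }
  p0 <- c(tochol(Sa), tochol(Sc), tochol(Se))
  expect_equal(-negll2(p0), fit$logLik, tolerance = 1e-3)
  o <- optim(p0, negll2, method = "Nelder-Mead",
             control = list(maxit = 800, reltol = 1e-10))
  expect_lt(-o$value - fit$logLik, 0.01)
  expect_true(abs(fit$rG$estimate) <= 1)
})

test_that("a null additive architecture is estimated at the boundary", {
  hs <- halfsib_data(ns = 100, no = 10, h2 = 0, seed = 77)
  fit <- animal_reml(y ~ 1, hs$data, hs$ped, litter = NULL)
  expect_lte(fit$h2[1, 1], 0.05)
})

test_that("variance ratios are invariant to affine rescaling of the trait", {
  fd <- family_data(ns = 25, h2 = 0.3, c2 = 0.1, seed = 33)
  f1 <- animal_reml(y ~ sex, fd$data, fd$ped)
  fd$data$y <- 10 * fd$data$y + 5
  f2 <- animal_reml(y ~ sex, fd$data, fd$ped)
  expect_equal(f1$h2[1, 1], f2$h2[1, 1], tolerance = 1e-4)
  expect_equal(f1$c2[1, 1], f2$c2[1, 1], tolerance = 1e-4)
  expect_equal(f2$varcomp$a[1] / f1$varcomp$a[1], 100, tolerance = 0.01)
})

test_that("a near-duplicated trait gives a genetic correlation near one", {
  fd <- family_data(ns = 25, h2 = 0.4, c2 = 0.05, seed = 51)
  fd$data$y2 <- fd$data$y + rnorm(nrow(fd$data), 0, 0.05)
  fd$data$y1 <- fd$data$y
  fit <- animal_reml(cbind(y1, y2) ~ sex, fd$data, fd$ped)
  expect_gt(fit$rG$estimate, 0.9)
})

test_that("independent traits give a genetic correlation near zero", {
  reps <- sapply(1:5, function(r) {
    fd <- family_data(ns = 40, h2 = 0.4, c2 = 0.05, seed = 60 + r,
                      rho = 0, h2b = 0.4)
    animal_reml(cbind(y1, y2) ~ sex, fd$data, fd$ped)$rG$estimate
  })
  expect_lt(abs(mean(reps)), 0.25)
})

test_that("parameter recovery holds across an h2 x c2 grid", {
  grid <- expand.grid(h2 = c(0.1, 0.3, 0.5), c2 = c(0, 0.1))
  means <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ests <- sapply(1:5, function(r) {
      fd <- family_data(ns = 30, h2 = grid$h2[i], c2 = grid$c2[i],
                        seed = 100 * i + r)
      animal_reml(y ~ sex, fd$data, fd$ped)$h2[1, 1]
    })
    means[i] <- mean(ests)
    # zero-truncation inflates small-h2 means on a design this size, so the
    # per-cell bound carries a boundary allowance on top of the MC error
    expect_lt(abs(means[i] - grid$h2[i]), 3 * sd(ests) / sqrt(5) + 0.08)
  }
  # the low and high architectures are clearly separated at both litter
  # levels (grid rows 1:3 are h2 = .1/.3/.5 at c2 = 0, rows 4:6 at c2 = 0.1;
  # adjacent cells are not required to order at this replicate count)
  expect_lt(means[1], means[3])
  expect_lt(means[4], means[6])
})

test_that("rank-deficient fixed effects are reported with the aliased term", {
  fd <- family_data(ns = 10, h2 = 0.3, c2 = 0.1, seed = 3)
  fd$data$sex2 <- fd$data$sex
  expect_error(animal_reml(y ~ sex + sex2, fd$data, fd$ped), "aliased")
})

test_that("binary enterotype heritability behaves at both extremes", {
  fd <- family_data(ns = 30, h2 = 0.4, c2 = 0.05, seed = 91)
  # labels fully determined by litter: no additive variance, large litter share
  lit_sign <- setNames(rbinom(length(unique(fd$data$litter)), 1, 0.5),
                       unique(fd$data$litter))
  fd$data$ent <- ifelse(lit_sign[fd$data$litter] == 1, "PM", "RT")
  fit <- heritability_binary(fd$data, "ent", ~ sex, fd$ped)
  expect_lt(fit$h2[1, 1], 0.1)
  expect_gt(fit$c2[1, 1], 0.5)
  # random labels: both shares near zero
  set.seed(4)
  fd$data$ent2 <- sample(c("PM", "RT"), nrow(fd$data), TRUE)
  fit2 <- heritability_binary(fd$data, "ent2", ~ sex, fd$ped)
  expect_lt(fit2$h2[1, 1], 0.15)
  expect_error(heritability_binary(transform(fd$data, ent3 = "PM"), "ent3",
                                   ~ sex, fd$ped), "single class")
  expect_true(is.finite(fit2$liability$h2_liab))
})

test_that("print and accessor methods work", {
  fd <- family_data(ns = 15, h2 = 0.3, c2 = 0.1, seed = 8)
  fit <- animal_reml(y ~ sex, fd$data, fd$ped)
  expect_output(print(fit), "h2")
  h <- heritability(fit)
  expect_named(h, c("trait", "h2", "h2_se", "c2", "c2_se"))
  expect_error(genetic_correlation(fit), "two-trait")
  expect_length(coef(fit), 2)
  expect_s3_class(logLik(fit), "logLik")
})
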