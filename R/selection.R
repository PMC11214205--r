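#' Breeding-scheme design parameters
#'
#' Defaults reproduce the published divergent-selection design: a founder
#' (G0) population of 30 litters from 30 sires x 30 dams, then per line and
#' generation 6 sires and 30 dams producing 30 litters, with recorded
#' offspring counts G0 = 316, G1 = 133 (HPM) / 139 (HRT), G2 = 114/114,
#' G3 = 126/125 (1067 phenotyped animals in total). Females leaving G0 are
#' picked on a litter basis (at most two per litter); later generations rank
#' females freely within the line.
#'
#' @param n_founder_sires,n_founder_dams founder counts.
#' @param counts named list of recorded offspring per generation; `G0` is a
#'   single number, later entries are named per-line vectors.
#' @param n_sires,n_dams,n_litters selected parents / litters per line and
#'   generation.
#' @param dams_per_sire mating ratio (n_dams / n_sires).
#' @param g1_litter_basis logical; apply the litter-basis rule when choosing
#'   the dams of G1.
#' @param batches_per_generation number of farrowing batches per generation
#'   (litters of both lines are spread across them).
#' @return A list of class `"breeding_scheme"`.
#' @export
breeding_scheme <- function(n_founder_sires = 30, n_founder_dams = 30,
                            counts = list(G0 = 316,
                                          G1 = c(HPM = 133, HRT = 139),
                                          G2 = c(HPM = 114, HRT = 114),
                                          G3 = c(HPM = 126, HRT = 125)),
                            n_sires = 6, n_dams = 30, n_litters = 30,
                            dams_per_sire = 5, g1_litter_basis = TRUE,
                            batches_per_generation = 3) {
  stopifnot(n_dams == n_sires * dams_per_sire, n_litters == n_dams)
  for (g in names(counts)[-1]) {
    if (any(counts[[g]] <= 0)) stop("offspring counts must be positive")
  }
  structure(as.list(environment()), class = "breeding_scheme")
}

#' Genetic architecture of the simulated traits
#'
#' Six traits are simulated on the phenotypic SD scale (variance 1 each):
#' the two HPM selection criteria (`prevotella`, `mitsuokella`), the two HRT
#' criteria (`treponema`, `ruminococcus`), the latent enterotype
#' `liability`, and post-weaning average daily gain (`adg`). The genetic
#' correlation matrix is built from a single-factor model,
#' `rG = L L' + diag(1 - L^2)`, with loadings `L` on a latent
#' "enterotype axis": taxa of the same enterotype are positively correlated,
#' taxa of opposite enterotypes negatively, growth is moderately correlated
#' (|rG| in the reported 0.32-0.52 band with the reported signs), and the
#' liability loading ties the enterotype to the selection criteria. The
#' factor construction guarantees a positive-definite matrix.
#'
#' @param h2 named per-trait heritabilities.
#' @param c2 named per-trait common-litter variance ratios.
#' @param loadings named factor loadings in (-1, 1) defining `rG`.
#' @param rG optional explicit correlation matrix overriding `loadings`
#'   (must be symmetric positive semidefinite with unit diagonal).
#' @param sex_effect additive fixed effect of male sex, in phenotypic SD.
#' @param batch_sd SD of the batch fixed effects, in phenotypic SD.
#' @param threshold liability threshold; `"g0_median"` (default) uses the
#'   median G0 liability phenotype, or a fixed number.
#' @return A list of class `"genetic_architecture"` with the assembled
#'   additive / litter / residual covariance matrices.
#' @export
genetic_architecture <- function(h2 = c(prevotella = 0.3, mitsuokella = 0.3,
                                        treponema = 0.3, ruminococcus = 0.3,
                                        liability = 0.3, adg = 0.2),
                                 c2 = c(prevotella = 0.05, mitsuokella = 0.05,
                                        treponema = 0.05, ruminococcus = 0.05,
                                        liability = 0.05, adg = 0.05),
                                 loadings = c(prevotella = 0.95, mitsuokella = 0.8,
                                              treponema = -0.95, ruminococcus = -0.8,
                                              liability = 1.0, adg = 0.5),
                                 rG = NULL,
                                 sex_effect = 0.15, batch_sd = 0.3,
                                 threshold = "g0_median") {
  traits <- names(h2)
  stopifnot(!is.null(traits), all(h2 >= 0), all(c2 >= 0), all(h2 + c2 <= 1))
  if (is.null(rG)) {
    L <- loadings[traits]
    if (any(is.na(L))) stop("loadings must cover all traits")
    rG <- tcrossprod(L) + diag(1 - L^2)
    dimnames(rG) <- list(traits, traits)
  } else {
    rG <- as.matrix(rG)
    if (!isSymmetric(unname(rG), tol = 1e-8)) stop("rG must be symmetric")
    if (any(abs(diag(rG) - 1) > 1e-8)) stop("rG must have unit diagonal")
    if (min(eigen(rG, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("rG must be positive semidefinite")
    }
  }
  sig_a <- diag(sqrt(h2), length(traits))
  Sigma_a <- sig_a %*% rG %*% sig_a
  dimnames(Sigma_a) <- list(traits, traits)
  structure(list(traits = traits, h2 = h2, c2 = c2, rG = rG,
                 Sigma_a = Sigma_a, sigma_c = sqrt(c2),
                 sigma_e = sqrt(1 - h2 - c2),
                 sex_effect = sex_effect, batch_sd = batch_sd,
                 threshold = threshold),
            class = "genetic_architecture")
}

# correlated MVN draws: n x t matrix with covariance Sigma
rmvn <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(stats::rnorm(n * ncol(Sigma)), n) %*% rt
}

#' Rank-and-pick sires under the two-stage intra-family rule
#'
#' Within each sire family, male candidates are ranked on the
#' (batch-precorrected) primary trait; among the top three (or all, if the
#' family has fewer males) the one with the highest secondary trait is the
#' family's pick; across families the `n_select` picks with the highest
#' primary values are kept ("one boar per sire"). Ties break on animal id.
#'
#' @param candidates data.frame of male candidates with columns `animal`,
#'   `family` (the sire id) and the two trait columns.
#' @param primary,secondary trait column names.
#' @param n_select number of sires to return.
#' @return Character vector of selected animal ids.
#' @export
select_sires <- function(candidates, primary, secondary, n_select = 6) {
  fams <- split(candidates, candidates$family)
  if (length(fams) < n_select) {
    stop("need at least ", n_select, " sire families with male candidates, got ", length(fams))
  }
  picks <- lapply(fams, function(f) {
    f <- f[order(-f[[primary]], f$animal), , drop = FALSE]
    top <- f[seq_len(min(3L, nrow(f))), , drop = FALSE]
    top <- top[order(-top[[secondary]], top$animal), , drop = FALSE]
    top[1, , drop = FALSE]
  })
  picks <- do.call(rbind, picks)
  picks <- picks[order(-picks[[primary]], picks$animal), , drop = FALSE]
  picks$animal[seq_len(n_select)]
}

#' Rank-and-pick dams, with the G1 litter-basis rule
#'
#' With `litter_basis = TRUE` (used when leaving the founder generation) the
#' best female of each litter is taken first, then the second-best per
#' litter, in decreasing order of the primary trait, never exceeding two per
#' litter, until `n_select` are chosen. Otherwise the global top `n_select`
#' on the primary trait are taken. Ties break on animal id.
#'
#' @param candidates data.frame of female candidates with columns `animal`,
#'   `litter` and the primary trait column.
#' @param primary trait column name.
#' @param n_select number of dams to return.
#' @param litter_basis logical; apply the per-litter cap-2 greedy rule.
#' @return Character vector of selected animal ids.
#' @export
select_dams <- function(candidates, primary, n_select = 30, litter_basis = FALSE) {
  if (nrow(candidates) < n_select) {
    stop("need at least ", n_select, " female candidates, got ", nrow(candidates))
  }
  ord <- candidates[order(-candidates[[primary]], candidates$animal), , drop = FALSE]
  if (!litter_basis) return(ord$animal[seq_len(n_select)])
  rank_in_litter <- stats::ave(seq_len(nrow(ord)), ord$litter, FUN = seq_along)
  first <- ord[rank_in_litter == 1, , drop = FALSE]
  second <- ord[rank_in_litter == 2, , drop = FALSE]
  chosen <- first$animal
  if (length(chosen) < n_select) chosen <- c(chosen, second$animal)
  if (length(chosen) < n_select) {
    stop("cannot select ", n_select, " dams with at most two per litter")
  }
  chosen[seq_len(n_select)]
}

#' Assign dams to sires, avoiding fullsib-halfsib matings
#'
#' Each sire receives `dams_per_sire` dams; a pair is forbidden when the two
#' animals share a recorded parent. The randomised assignment is found by
#' depth-first search with backtracking.
#'
#' @param sires,dams animal id vectors (length `n` and `n * dams_per_sire`).
#' @param ped_df data.frame with columns `animal`, `sire`, `dam` covering
#'   both parent sets (used for the shared-parent test).
#' @param dams_per_sire matings per sire.
#' @return data.frame with columns `sire`, `dam`.
#' @export
mate_pairs <- function(sires, dams, ped_df, dams_per_sire = 5) {
  stopifnot(length(dams) == length(sires) * dams_per_sire)
  par_of <- function(ids) {
    i <- match(ids, ped_df$animal)
    cbind(ped_df$sire[i], ped_df$dam[i])
  }
  ps <- par_of(sires); pd <- par_of(dams)
  n_s <- length(sires); n_d <- length(dams)
  feasible <- matrix(TRUE, n_s, n_d)
  for (si in seq_len(n_s)) for (di in seq_len(n_d)) {
    a <- ps[si, ]; b <- pd[di, ]
    feasible[si, di] <- !(any(!is.na(a) & !is.na(b[1]) & a == b[1]) ||
                            any(!is.na(a) & !is.na(b[2]) & a == b[2]))
  }
  # most-constrained dams first keeps the backtracking shallow
  order_d <- order(colSums(feasible) + stats::runif(n_d, 0, 0.5))
  cap <- rep(dams_per_sire, n_s)
  assign <- integer(n_d)
  nodes <- 0L
  ok <- function(pos) {
    if (pos > n_d) return(TRUE)
    nodes <<- nodes + 1L
    if (nodes > 2e5) return(NA)   # search limit: treat as infeasible
    di <- order_d[pos]
    cand <- which(cap > 0 & feasible[, di])
    if (length(cand) > 1) cand <- sample(cand)
    for (si in cand) {
      assign[di] <<- si
      cap[si] <<- cap[si] - 1L
      res <- ok(pos + 1)
      if (isTRUE(res)) return(TRUE)
      cap[si] <<- cap[si] + 1L
      assign[di] <<- 0L
      if (is.na(res)) return(NA)
    }
    FALSE
  }
  if (!isTRUE(ok(1))) {
    stop("no feasible balanced mating plan; ", sum(!feasible), " of ",
         n_s * n_d, " sire-dam pairs are forbidden")
  }
  data.frame(sire = sires[assign], dam = dams, stringsAsFactors = FALSE)
}

#' Simulate the divergent holobiont-selection experiment
#'
#' Simulates the full three-generation scheme: founders receive multivariate
#' normal breeding values with covariance `Sigma_a`; offspring breeding
#' values are midparent plus a Mendelian deviation with per-trait variance
#' `Sigma_a / 2 * (1 - (F_s + F_d)/2)` correlated across traits; phenotypes
#' add a sex effect, a farrowing-batch effect, a litter deviation shared by
#' littermates, and an independent residual. Each animal's enterotype is PM
#' when its liability phenotype exceeds the threshold (the G0 median by
#' default). Selection follows the published rules: intra-sire two-stage
#' ranking of boars (primary then secondary taxon, one boar per sire),
#' within-line ranking of females (litter-based out of G0), balanced matings
#' avoiding fullsib-halfsib pairs. The HPM line selects on
#' prevotella/mitsuokella, the HRT line on treponema/ruminococcus (both on
#' batch-precorrected phenotypes).
#'
#' @param scheme a [breeding_scheme()].
#' @param arch a [genetic_architecture()].
#' @param seed integer seed (all randomness derives from it).
#' @param select logical; `FALSE` replaces trait-based selection with random
#'   choice of parents (null scheme for parameter-recovery studies).
#' @return A list of class `"sim_population"`: `ped` (pedigree data.frame
#'   with generation, line, sex, litter, batch), `pheno` (animals x traits
#'   phenotype matrix), `bv` (breeding values), `enterotype` (PM/RT for
#'   phenotyped animals), `threshold`.
#' @export
simulate_population <- function(scheme = breeding_scheme(),
                                arch = genetic_architecture(),
                                seed = 1, select = TRUE) {
  set.seed(as.integer(seed))
  traits <- arch$traits
  nt <- length(traits)
  if (select && !all(c("prevotella", "mitsuokella", "treponema", "ruminococcus") %in% traits)) {
    stop("trait-based selection needs the four selection-criterion traits; ",
         "use select = FALSE for custom trait sets")
  }
  gens <- setdiff(names(scheme$counts), "G0")
  n_total <- scheme$n_founder_sires + scheme$n_founder_dams +
    scheme$counts$G0 + sum(unlist(scheme$counts[gens]))
  A <- matrix(0, n_total, n_total)
  ped <- data.frame(animal = character(n_total), sire = NA_character_,
                    dam = NA_character_, generation = NA_character_,
                    line = NA_character_, sex = NA_character_,
                    litter = NA_character_, batch = NA_character_,
                    stringsAsFactors = FALSE)
  bv <- matrix(NA_real_, n_total, nt, dimnames = list(NULL, traits))
  pheno <- matrix(NA_real_, n_total, nt, dimnames = list(NULL, traits))
  n_cur <- 0L
  idx_of <- new.env(hash = TRUE)

  add_founders <- function(ids, sex) {
    for (k in seq_along(ids)) {
      i <- n_cur + k
      A[i, i] <<- 1
      ped$animal[i] <<- ids[k]
      ped$sex[i] <<- sex
      ped$generation[i] <<- "F"
      assign(ids[k], i, envir = idx_of)
    }
    bv[n_cur + seq_along(ids), ] <<- rmvn(length(ids), arch$Sigma_a)
    n_cur <<- n_cur + length(ids)
  }
  add_offspring <- function(sire_id, dam_id, n_off, gen, line, litter_id, batch_id,
                            batch_eff, litter_eff) {
    s <- get(sire_id, envir = idx_of); d <- get(dam_id, envir = idx_of)
    rows <- n_cur + seq_len(n_off)
    Fs <- A[s, s] - 1; Fd <- A[d, d] - 1
    mend <- rmvn(n_off, arch$Sigma_a * 0.5 * (1 - (Fs + Fd) / 2))
    bv[rows, ] <<- rep((bv[s, ] + bv[d, ]) / 2, each = n_off) + mend
    sexes <- ifelse(stats::runif(n_off) < 0.5, "M", "F")
    for (k in seq_len(n_off)) {
      i <- rows[k]
      old <- seq_len(i - 1L)
      arow <- (A[s, old] + A[d, old]) / 2
      A[i, old] <<- arow
      A[old, i] <<- arow
      A[i, i] <<- 1 + A[s, d] / 2
      id <- sprintf("%s_%s_%04d", gen, line, i)
      ped$animal[i] <<- id
      ped$sire[i] <<- sire_id; ped$dam[i] <<- dam_id
      ped$generation[i] <<- gen; ped$line[i] <<- line
      ped$sex[i] <<- sexes[k]
      ped$litter[i] <<- litter_id; ped$batch[i] <<- batch_id
      assign(id, i, envir = idx_of)
      n_cur <<- n_cur + 1L
    }
    resid <- matrix(stats::rnorm(n_off * nt), n_off) %*% diag(arch$sigma_e, nt)
    sexeff <- (sexes == "M") * arch$sex_effect
    pheno[rows, ] <<- bv[rows, ] +
      rep(litter_eff, each = n_off) + resid +
      outer(sexeff, rep(1, nt)) +
      rep(batch_eff, each = n_off)
  }
  breed_generation <- function(matings, targets, gen, line_of_mating) {
    # matings: data.frame(sire, dam); targets: named per-line offspring totals
    n_lit <- nrow(matings)
    batch_ids <- paste0(gen, "_B", (seq_len(n_lit) %% scheme$batches_per_generation) + 1L)
    batch_levels <- unique(batch_ids)
    beff <- matrix(stats::rnorm(length(batch_levels) * nt, 0, arch$batch_sd),
                   length(batch_levels), nt, dimnames = list(batch_levels, NULL))
    for (line in unique(line_of_mating)) {
      rows <- which(line_of_mating == line)
      sizes <- as.vector(stats::rmultinom(1, targets[[line]], rep(1, length(rows))))
      for (j in seq_along(rows)) {
        if (sizes[j] == 0) next
        r <- rows[j]
        litter_id <- sprintf("%s_%s_L%02d", gen, line, j)
        add_offspring(matings$sire[r], matings$dam[r], sizes[j], gen, line,
                      litter_id, batch_ids[r], beff[batch_ids[r], ],
                      stats::rnorm(nt, 0, arch$sigma_c))
      }
    }
  }
  precorrect <- function(rows) {
    # residuals of the batch fixed effect, per trait, within the candidate set
    ph <- pheno[rows, , drop = FALSE]
    b <- factor(ped$batch[rows])
    if (nlevels(b) > 1) {
      for (t in seq_len(nt)) ph[, t] <- stats::resid(stats::lm(ph[, t] ~ b))
    }
    ph
  }
  pick_parents <- function(rows, line, litter_basis) {
    ph <- precorrect(rows)
    crit <- if (line == "HPM") c("prevotella", "mitsuokella") else c("treponema", "ruminococcus")
    cand <- data.frame(animal = ped$animal[rows], family = ped$sire[rows],
                       litter = ped$litter[rows], sex = ped$sex[rows],
                       p1 = ph[, crit[1]], p2 = ph[, crit[2]],
                       stringsAsFactors = FALSE)
    males <- cand[cand$sex == "M", ]
    females <- cand[cand$sex == "F", ]
    n_fam <- length(unique(males$family))
    if (n_fam >= scheme$n_sires) {
      sires <- select_sires(males, "p1", "p2", n_select = scheme$n_sires)
    } else {
      # a family without sons cannot supply a boar: fill the open slots with
      # the best remaining males regardless of family
      sires <- select_sires(males, "p1", "p2", n_select = n_fam)
      rest <- males[!(males$animal %in% sires), ]
      rest <- rest[order(-rest$p1, rest$animal), ]
      sires <- c(sires, rest$animal[seq_len(scheme$n_sires - n_fam)])
    }
    dams <- select_dams(females, "p1", n_select = scheme$n_dams,
                        litter_basis = litter_basis)
    list(sires = sires, dams = dams)
  }
  pick_random <- function(rows) {
    males <- ped$animal[rows][ped$sex[rows] == "M"]
    females <- ped$animal[rows][ped$sex[rows] == "F"]
    # spread random sires across sire families (as the real scheme does) so
    # that a balanced non-sib mating plan stays feasible
    fam <- ped$sire[rows][ped$sex[rows] == "M"]
    by_fam <- split(males, fam)
    picks <- vapply(by_fam, function(v) v[sample.int(length(v), 1)], character(1))
    sires <- if (length(picks) >= scheme$n_sires) {
      sample(picks, scheme$n_sires)
    } else {
      c(picks, sample(setdiff(males, picks), scheme$n_sires - length(picks)))
    }
    list(sires = unname(sires), dams = sample(females, scheme$n_dams))
  }

  # founders and G0
  sire_ids <- sprintf("FS%02d", seq_len(scheme$n_founder_sires))
  dam_ids <- sprintf("FD%02d", seq_len(scheme$n_founder_dams))
  add_founders(sire_ids, "M")
  add_founders(dam_ids, "F")
  g0_matings <- data.frame(sire = sire_ids, dam = dam_ids, stringsAsFactors = FALSE)
  breed_generation(g0_matings, list(G0 = scheme$counts$G0), "G0",
                   rep("G0", nrow(g0_matings)))

  prev_rows <- list(HPM = which(ped$generation == "G0"),
                    HRT = which(ped$generation == "G0"))
  taken <- character(0)
  for (g_i in seq_along(gens)) {
    gen <- gens[g_i]
    all_matings <- NULL; line_of <- character(0)
    for (line in c("HPM", "HRT")) {
      rows <- prev_rows[[line]]
      rows <- rows[!(ped$animal[rows] %in% taken)]
      parents <- if (select) {
        pick_parents(rows, line, litter_basis = (g_i == 1 && scheme$g1_litter_basis))
      } else pick_random(rows)
      if (g_i == 1) taken <- c(taken, parents$sires, parents$dams)
      m <- mate_pairs(parents$sires, parents$dams, ped[seq_len(n_cur), ],
                      dams_per_sire = scheme$dams_per_sire)
      all_matings <- rbind(all_matings, m)
      line_of <- c(line_of, rep(line, nrow(m)))
    }
    breed_generation(all_matings, as.list(scheme$counts[[gen]]), gen, line_of)
    for (line in c("HPM", "HRT")) {
      prev_rows[[line]] <- which(ped$generation == gen & ped$line == line)
    }
  }

  ped <- ped[seq_len(n_cur), , drop = FALSE]
  pheno <- pheno[seq_len(n_cur), , drop = FALSE]
  bv <- bv[seq_len(n_cur), , drop = FALSE]
  rownames(pheno) <- rownames(bv) <- ped$animal
  g0 <- which(ped$generation == "G0")
  if ("liability" %in% traits) {
    thr <- if (identical(arch$threshold, "g0_median")) {
      stats::median(pheno[g0, "liability"])
    } else arch$threshold
    enterotype <- ifelse(pheno[, "liability"] > thr, "PM", "RT")
    enterotype[is.na(pheno[, "liability"])] <- NA
  } else {
    thr <- NA_real_
    enterotype <- rep(NA_character_, nrow(ped))
  }
  structure(list(ped = ped, pheno = pheno, bv = bv,
                 enterotype = enterotype, threshold = thr,
                 scheme = scheme, arch = arch, seed = seed),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$ped$generation)
  cat("simulated population:", nrow(x$ped), "animals\n")
  print(tab)
  invisible(x)
}

#' Run the breeding scheme over replicates and summarise trajectories
#'
#' @param scheme a [breeding_scheme()].
#' @param arch a [genetic_architecture()].
#' @param n_replicates number of independent simulation replicates.
#' @param seed base seed; replicate `r` uses `seed + r - 1`.
#' @param select passed to [simulate_population()].
#' @return A list with `trajectory` (one row per replicate x line x
#'   generation: PM prevalence in percent, mean taxon phenotypes, mean adg)
#'   and `summary` (across-replicate mean and Monte-Carlo SE).
#' @export
run_scheme <- function(scheme = breeding_scheme(), arch = genetic_architecture(),
                       n_replicates = 50, seed = 1, select = TRUE) {
  traj <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    pop <- simulate_population(scheme, arch, seed = as.integer(seed) + r - 1L,
                               select = select)
    ped <- pop$ped
    grp <- ifelse(ped$generation == "G0", "G0", ped$line)
    keep <- ped$generation %in% c("G0", setdiff(names(scheme$counts), "G0"))
    df <- data.frame(replicate = r, line = grp[keep],
                     generation = ped$generation[keep],
                     pm = pop$enterotype[keep] == "PM",
                     pop$pheno[keep, , drop = FALSE],
                     stringsAsFactors = FALSE)
    agg <- stats::aggregate(df[, -(1:3)],
                            by = list(line = df$line, generation = df$generation),
                            FUN = mean)
    agg$pm <- 100 * agg$pm
    names(agg)[names(agg) == "pm"] <- "pm_prevalence"
    agg$replicate <- r
    traj[[r]] <- agg
  }
  traj <- do.call(rbind, traj)
  num <- setdiff(names(traj), c("line", "generation", "replicate"))
  mean_tab <- stats::aggregate(traj[num], by = list(line = traj$line, generation = traj$generation), FUN = mean)
  se_tab <- stats::aggregate(traj[num], by = list(line = traj$line, generation = traj$generation),
                             FUN = function(v) stats::sd(v) / sqrt(length(v)))
  list(trajectory = traj, summary = mean_tab, mc_se = se_tab)
}
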