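test_that("the scheme defaults reproduce the printed design", {
  sc <- breeding_scheme()
  expect_equal(sc$counts$G0, 316)
  expect_equal(sum(unlist(sc$counts[-1])), 751)
  expect_equal(sc$counts$G0 + sum(unlist(sc$counts[-1])), 1067)
  expect_equal(unname(sc$counts$G1), c(133, 139))
  expect_equal(sc$n_sires, 6); expect_equal(sc$n_dams, 30)
  expect_error(breeding_scheme(n_dams = 31), "n_dams == n_sires")
})

test_that("the default architecture has a valid positive-definite rG", {
  arch <- genetic_architecture()
  ev <- eigen(arch$rG, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_equal(unname(diag(arch$rG)), rep(1, 6))
  # within-enterotype positive, between negative, ADG in the reported band
  expect_gt(arch$rG["prevotella", "mitsuokella"], 0)
  expect_lt(arch$rG["prevotella", "treponema"], -0.9)
  expect_true(all(abs(arch$rG["adg", c("prevotella", "mitsuokella",
                                       "treponema", "ruminococcus")]) >= 0.32))
  expect_true(all(abs(arch$rG["adg", c("prevotella", "mitsuokella",
                                       "treponema", "ruminococcus")]) <= 0.52))
  expect_gt(arch$rG["adg", "prevotella"], 0)   # growth favours the PM side
  expect_lt(arch$rG["adg", "treponema"], 0)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(genetic_architecture(h2 = c(a = .3, b = .3), c2 = c(a = 0, b = 0),
                                    rG = bad), "positive semidefinite")
})

test_that("select_sires applies the two-stage intra-family rule", {
  cand <- data.frame(animal = c("m1", "m2", "m3", "m4"),
                     family = "F1",
                     p1 = c(9, 8, 7, 1), p2 = c(0.1, 0.9, 0.5, 2.0))
  # top three on p1 are m1, m2, m3; among them m2 has the highest p2
  expect_equal(select_sires(cand, "p1", "p2", n_select = 1), "m2")
  # equal secondary values: primary rank then id breaks the tie
  cand$p2 <- 1
  expect_equal(select_sires(cand, "p1", "p2", n_select = 1), "m1")
  # across families, the n best family picks by primary are kept
  cand6 <- data.frame(animal = paste0("m", 1:8), family = rep(paste0("F", 1:4), 2),
                      p1 = c(5, 6, 7, 8, 1, 2, 3, 4), p2 = 1)
  picks <- select_sires(cand6, "p1", "p2", n_select = 2)
  expect_setequal(picks, c("m4", "m3"))
  expect_error(select_sires(cand, "p1", "p2", n_select = 6), "at least 6")
})

test_that("select_dams applies the litter-cap greedy rule for G1", {
  # 20 litters, two females each: best-per-litter first, then second-best
  cand <- data.frame(animal = sprintf("f%02d", 1:40),
                     litter = rep(sprintf("L%02d", 1:20), each = 2),
                     p1 = seq(40, 1))
  sel <- select_dams(cand, "p1", n_select = 30, litter_basis = TRUE)
  expect_length(sel, 30)
  expect_true(all(table(cand$litter[match(sel, cand$animal)]) <= 2))
  # the best female of every litter is included
  firsts <- cand$animal[seq(1, 40, by = 2)]
  expect_true(all(firsts %in% sel))
  # later generations: global top 30
  sel2 <- select_dams(cand, "p1", n_select = 30, litter_basis = FALSE)
  expect_equal(sel2, cand$animal[1:30])
  expect_error(select_dams(cand[1:10, ], "p1", 30), "at least 30")
})

test_that("mate_pairs balances sires and avoids shared-parent matings", {
  ped_df <- data.frame(animal = c(paste0("s", 1:3), paste0("d", 1:15), "pa", "pb"),
                       sire = c("pa", NA, NA, "pa", rep(NA, 14), NA, NA),
                       dam = c("pb", NA, NA, "pb", rep(NA, 14), NA, NA))
  set.seed(1)
  for (i in 1:25) {
    m <- mate_pairs(paste0("s", 1:3), paste0("d", 1:15), ped_df, dams_per_sire = 5)
    expect_equal(as.vector(table(m$sire)), rep(5L, 3))
    # d1 is a full sib of s1: that pair must never occur
    expect_false(any(m$sire == "s1" & m$dam == "d1"))
  }
  # infeasible: every dam a full sib of every sire
  ped_bad <- data.frame(animal = c("x", "y", "s1", "d1", "d2"),
                        sire = c(NA, NA, "x", "x", "x"),
                        dam = c(NA, NA, "y", "y", "y"))
  expect_error(mate_pairs("s1", c("d1", "d2"), ped_bad, dams_per_sire = 2),
               "no feasible")
})

test_that("simulated populations honour the printed counts and pedigree rules", {
  pop <- simulate_population(seed = 77)
  tab <- table(pop$ped$generation)
  expect_equal(as.vector(tab[c("G0", "G1", "G2", "G3")]), c(316L, 272L, 228L, 251L))
  expect_equal(sum(pop$ped$generation != "F"), 1067)
  byline <- table(pop$ped$generation, pop$ped$line)
  expect_equal(as.vector(byline["G1", c("HPM", "HRT")]), c(133L, 139L))
  expect_equal(as.vector(byline["G3", c("HPM", "HRT")]), c(126L, 125L))
  # the pedigree validates (acyclic, parents first) and littermates share dams
  ped <- pedigree(pop$ped[, c("animal", "sire", "dam")])
  expect_s3_class(ped, "pedigree")
  lit <- split(pop$ped$dam[!is.na(pop$ped$litter)], pop$ped$litter[!is.na(pop$ped$litter)])
  expect_true(all(vapply(lit, function(v) length(unique(v)) == 1, logical(1))))
  # no mating between animals sharing a parent
  prow <- match(pop$ped$animal, pop$ped$animal)
  par_of <- function(id) unlist(pop$ped[match(id, pop$ped$animal), c("sire", "dam")])
  mated <- unique(pop$ped[!is.na(pop$ped$sire), c("sire", "dam")])
  shared <- apply(mated, 1, function(r) {
    length(intersect(na.omit(par_of(r[1])), na.omit(par_of(r[2])))) > 0
  })
  expect_false(any(shared))
})

test_that("offspring breeding values are midparent plus Mendelian deviation", {
  pop <- simulate_population(seed = 5, select = FALSE)
  ped <- pop$ped
  kids <- which(ped$generation == "G1")
  mid <- (pop$bv[match(ped$sire[kids], ped$animal), "liability"] +
            pop$bv[match(ped$dam[kids], ped$animal), "liability"]) / 2
  dev <- pop$bv[kids, "liability"] - mid
  # deviations centre on zero with variance ~ sigma2_a / 2
  expect_lt(abs(mean(dev)), 0.1)
  expect_equal(var(dev), 0.5 * 0.3, tolerance = 0.35)
})

test_that("selection shifts enterotype prevalence while random mating does not", {
  rs <- run_scheme(n_replicates = 3, seed = 11)
  tr <- rs$trajectory
  hpm3 <- mean(tr$pm_prevalence[tr$line == "HPM" & tr$generation == "G3"])
  hrt3 <- mean(tr$pm_prevalence[tr$line == "HRT" & tr$generation == "G3"])
  expect_gt(hpm3, 60); expect_lt(hrt3, 40)
  rs0 <- run_scheme(n_replicates = 3, seed = 11, select = FALSE)
  tr0 <- rs0$trajectory
  flat <- tr0$pm_prevalence[tr0$generation == "G3"]
  # drift through 6 sires per line moves single replicates, not the average
  expect_lt(abs(mean(flat) - 50), 15)
})

test_that("line labels mirror under a mirrored architecture", {
  # swapping the roles of the PM and RT taxa flips the response direction
  arch <- genetic_architecture()
  sw <- genetic_architecture(loadings = c(prevotella = -0.95, mitsuokella = -0.8,
                                          treponema = 0.95, ruminococcus = 0.8,
                                          liability = 1.0, adg = 0.5))
  a <- run_scheme(arch = arch, n_replicates = 2, seed = 3)$trajectory
  b <- run_scheme(arch = sw, n_replicates = 2, seed = 3)$trajectory
  g3a <- mean(a$pm_prevalence[a$line == "HPM" & a$generation == "G3"])
  g3b <- mean(b$pm_prevalence[b$line == "HPM" & b$generation == "G3"])
  expect_gt(g3a, 55)   # selection for the PM side raises PM prevalence
  expect_lt(g3b, 45)   # with mirrored loadings the same line is dragged down
})

test_that("one-generation mass selection obeys the breeder's equation", {
  # no family structure: unrelated parents, select top half on phenotype
  set.seed(99)
  h2 <- 0.3
  n <- 4000
  resp <- replicate(6, {
    bv <- rnorm(n, 0, sqrt(h2))
    y <- bv + rnorm(n, 0, sqrt(1 - h2))
    sel <- order(-y)[seq_len(n / 2)]
    s_diff <- mean(y[sel])
    # offspring of random pairs of selected parents
    pa <- sample(sel); pairs1 <- pa[seq_len(n / 4)]; pairs2 <- pa[n / 4 + seq_len(n / 4)]
    mid <- (bv[pairs1] + bv[pairs2]) / 2
    off <- mid + rnorm(n / 4, 0, sqrt(h2 / 2)) + rnorm(n / 4, 0, sqrt(1 - h2))
    c(mean(off), h2 * s_diff)
  })
  realized <- mean(resp[1, ]); predicted <- mean(resp[2, ])
  mc_se <- sd(resp[1, ] - resp[2, ]) / sqrt(6)
  expect_lt(abs(realized - predicted), 3 * mc_se + 0.02)
})

test_that("null heritability keeps prevalence at coin-flip levels", {
  arch0 <- genetic_architecture(h2 = c(prevotella = 0, mitsuokella = 0,
                                       treponema = 0, ruminococcus = 0,
                                       liability = 0, adg = 0))
  rs <- run_scheme(arch = arch0, n_replicates = 3, seed = 21)
  g3 <- rs$trajectory$pm_prevalence[rs$trajectory$generation == "G3"]
  # shared farrowing-batch noise moves single generation means; the average
  # across replicates and lines stays at the coin-flip level
  expect_lt(abs(mean(g3) - 50), 12)
})
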