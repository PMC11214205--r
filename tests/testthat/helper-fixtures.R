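# shared fixtures, all built in code

# small count table with named taxa incl. the selection-target genera
toy_counts <- function(n = 12, depth = 5000, seed = 42) {
  set.seed(seed)
  taxa <- c("Prevotella_9", "Prevotella_7", "Prevotella", "Mitsuokella",
            "Treponema", "Ruminococcus", paste0("G", 1:14))
  probs <- c(0.3, 0.08, 0.05, 0.04, 0.1, 0.03, rep(0.02, 14))
  x <- t(stats::rmultinom(n, depth, probs))
  rownames(x) <- paste0("S", seq_len(n))
  colnames(x) <- taxa
  abundance_table(x, kind = "counts")
}

# pedigree of a nuclear family: 2 unrelated parents, k fullsib offspring
fam_pedigree <- function(k = 2) {
  pedigree(data.frame(animal = c("p1", "p2", paste0("o", seq_len(k))),
                      sire = c(NA, NA, rep("p1", k)),
                      dam = c(NA, NA, rep("p2", k))))
}

# independent kinship oracle: recursive coefficient of coancestry
# phi(i,j) memoised on the pedigree data.frame; a_ij = 2 phi(i,j)
kinship_oracle <- function(ped) {
  ped <- as.data.frame(ped)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    # ensure i is not older than j (appears later or equal)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    s <- idx[ped$sire[i]]; d <- idx[ped$dam[i]]
    s <- if (is.na(s)) 0 else s; d <- if (is.na(d)) 0 else d
    val <- if (i == j) {
      0.5 * (1 + phi(s, d))
    } else {
      0.5 * (phi(s, j) + phi(d, j))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    K[i, j] <- K[j, i] <- 2 * phi(i, j)
  }
  K
}

# random probability vector
rprob <- function(m) { p <- stats::rexp(m); p / sum(p) }

# exhaustive PAM oracle: best assignment over all medoid pairs (k = 2)
pam_oracle_k2 <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  best <- NULL; best_cost <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(dm[, i], dm[, j]))
    if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
  }
  list(medoids = best, cost = best_cost,
       clustering = apply(cbind(dm[, best[1]], dm[, best[2]]), 1, which.min))
}
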