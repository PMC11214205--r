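#' Square-root Jensen-Shannon divergence between two probability vectors
#'
#' Returns `sqrt(JSD(P, Q))` with `JSD = KL(P||M)/2 + KL(Q||M)/2`,
#' `M = (P+Q)/2`, natural logarithm. The square root of the Jensen-Shannon
#' divergence is a metric, bounded by `sqrt(log(2))`. Zeros are replaced by a
#' 1e-12 pseudo-count and the vectors renormalised before evaluation.
#'
#' @param p,q non-negative vectors of equal length, each summing to 1
#'   (within 1e-8).
#' @return Non-negative scalar distance.
#' @export
jsd_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("probability vectors differ in length")
  if (any(p < 0) || any(q < 0)) stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("probability vectors must sum to 1")
  }
  p <- pmax(p, 1e-12); p <- p / sum(p)
  q <- pmax(q, 1e-12); q <- q / sum(q)
  m <- (p + q) / 2
  jsd <- sum(p * log(p / m)) / 2 + sum(q * log(q / m)) / 2
  sqrt(max(jsd, 0))
}

plogp <- function(x) ifelse(x > 0, x * log(x), 0)

#' Pairwise sqrt-JSD distance matrix for an abundance table
#'
#' Rows are converted to proportions (zeros replaced by a 1e-12 pseudo-count,
#' then renormalised) and all pairwise square-root Jensen-Shannon divergences
#' are computed via the entropy identity `JSD(P,Q) = H(M) - (H(P)+H(Q))/2`.
#'
#' @param table an `abundance_table` (counts or relative).
#' @return A `dist` object of sqrt-JSD distances.
#' @export
jsd_distance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- unclass(table)
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("all-zero sample(s): ", paste(rownames(x)[rs <= 0], collapse = ", "))
  p <- x / rs
  p <- pmax(p, 1e-12)
  p <- p / rowSums(p)
  n <- nrow(p)
  h <- -rowSums(plogp(p))
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) {
    idx <- (i + 1):n
    m <- (p[idx, , drop = FALSE] + rep(p[i, ], each = length(idx))) / 2
    hm <- -rowSums(plogp(m))
    jsd <- pmax(hm - (h[idx] + h[i]) / 2, 0)
    d[i, idx] <- d[idx, i] <- sqrt(jsd)
  }
  stats::as.dist(d)
}

#' Partition samples around medoids (PAM) on a distance matrix
#'
#' Standard PAM with a randomised initial medoid set (drawn under `seed`)
#' followed by the swap phase; deterministic for a given seed.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param k number of clusters (2 <= k < n).
#' @param seed integer seed for the initial medoid draw; `NULL` uses the
#'   deterministic build phase instead.
#' @return A list with `clustering` (named integer vector), `medoids`
#'   (sample ids) and `cost` (sum of distances to the assigned medoid).
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 2) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of samples")
  init <- NULL
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    init <- sort(sample.int(n, k))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE, medoids = init,
                      do.swap = TRUE, pamonce = FALSE)
  labs <- attr(d, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(n))
  clustering <- stats::setNames(as.integer(fit$clustering), labs)
  dm <- as.matrix(d)
  med_idx <- match(if (is.character(fit$medoids)) fit$medoids else labs[fit$medoids], labs)
  cost <- sum(dm[cbind(seq_len(n), med_idx[clustering])])
  list(clustering = clustering, medoids = labs[med_idx], cost = cost)
}

#' Calinski-Harabasz index for a partition of a distance matrix
#'
#' Distance-based form: with `SST = sum(d^2)/n` over all pairs and
#' `SSW = sum over clusters of within-cluster sum(d^2)/n_c`, the index is
#' `((SST - SSW)/(k-1)) / (SSW/(n-k))`.
#'
#' @param d distance matrix or `dist`.
#' @param clustering integer cluster memberships.
#' @return Scalar index (larger is better separation).
#' @export
ch_index <- function(d, clustering) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  k <- length(unique(clustering))
  sst <- sum(dm) / (2 * n)
  ssw <- 0
  for (cl in unique(clustering)) {
    idx <- which(clustering == cl)
    ssw <- ssw + sum(dm[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' Choose the number of clusters by the Calinski-Harabasz index
#'
#' Runs [pam_cluster()] for each candidate `k` and returns the `k`
#' maximising [ch_index()]; the full index profile is attached as an
#' attribute.
#'
#' @param d distance matrix or `dist`.
#' @param k_range candidate cluster numbers (subset of `2:(n-1)`).
#' @param seed integer seed passed to each PAM run.
#' @return Integer `k` with attribute `"profile"` (named index vector).
#' @export
optimal_k <- function(d, k_range = 2:10, seed = 1) {
  if (!length(k_range)) stop("k_range is empty")
  n <- attr(stats::as.dist(d), "Size")
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) stop("k_range contains no feasible k")
  prof <- vapply(k_range, function(k) {
    ch_index(d, pam_cluster(d, k, seed = seed)$clustering)
  }, numeric(1))
  names(prof) <- k_range
  structure(k_range[which.max(prof)], profile = prof)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centred eigendecomposition of the squared distance matrix;
#' coordinates are ordered by decreasing eigenvalue and negative eigenvalues
#' are reported.
#'
#' @param d distance matrix or `dist`.
#' @param n_axes number of axes to return.
#' @return A list with `coordinates` (samples x axes) and `eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = min(n_axes, n - 1), eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < n_axes) {
    warning("requested more axes than the rank of the configuration; truncated")
    if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  }
  if (ncol(pts) == 0) pts <- matrix(0, n, 1, dimnames = list(attr(d, "Labels"), NULL))
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(coordinates = pts, eigenvalues = fit$eig)
}

#' Assign samples to the PM / RT enterotypes with a stability filter
#'
#' Clusters the table into two groups with sqrt-JSD + PAM repeatedly
#' (`iterations` runs from distinct random medoid initialisations), labels
#' each run's clusters by the mean abundance of the PM anchor taxa
#' (Prevotella-group plus Mitsuokella; the cluster with the higher mean is
#' PM), and reports per sample the modal label and the fraction of runs
#' agreeing with it. Samples whose label ever changed (`stability < 1`) are
#' marked `"unstable"` when `stability_filter = TRUE`, mirroring the practice
#' of retaining only animals that never change group across 100 repeats.
#'
#' @param table an `abundance_table`.
#' @param iterations number of clustering repeats.
#' @param seed integer seed; run `i` uses `seed + i - 1` for its medoid draw.
#' @param pm_anchors taxon labels whose summed abundance anchors the PM label.
#' @param stability_filter logical; mark ever-switching samples `"unstable"`.
#' @return data.frame with `sample_id`, `label` (`"PM"`, `"RT"` or
#'   `"unstable"`) and `stability` in `[0, 1]`.
#' @export
assign_enterotypes <- function(table, iterations = 100, seed = 1,
                               pm_anchors = c("Prevotella", "Prevotella_9",
                                              "Prevotella_7", "Prevotella_sum",
                                              "Mitsuokella"),
                               stability_filter = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table) < 4) stop("need at least 4 samples")
  anchors <- intersect(pm_anchors, colnames(table))
  if (!length(anchors)) stop("none of the PM anchor taxa are present in the table")
  x <- unclass(table)
  anchor_score <- rowSums(x[, anchors, drop = FALSE]) / rowSums(x)
  d <- jsd_distance(table)
  n <- nrow(x)
  pm_votes <- integer(n)
  for (it in seq_len(iterations)) {
    cl <- pam_cluster(d, k = 2, seed = as.integer(seed) + it - 1L)$clustering
    m1 <- mean(anchor_score[cl == 1]); m2 <- mean(anchor_score[cl == 2])
    pm_cluster_id <- if (m1 >= m2) 1L else 2L  # tie -> cluster 1 is PM
    pm_votes <- pm_votes + as.integer(cl == pm_cluster_id)
  }
  frac_pm <- pm_votes / iterations
  modal <- ifelse(frac_pm >= 0.5, "PM", "RT")
  stability <- pmax(frac_pm, 1 - frac_pm)
  label <- modal
  if (stability_filter) label[stability < 1] <- "unstable"
  data.frame(sample_id = rownames(x), label = label, stability = stability,
             modal_label = modal, row.names = NULL, stringsAsFactors = FALSE)
}
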