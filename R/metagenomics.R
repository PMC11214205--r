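#' Length-normalise a gene count matrix
#'
#' Raw gene counts are divided by gene length in kilobases. With
#' `relative = TRUE` each sample's normalised vector is additionally divided
#' by its sum, removing sequencing-depth effects.
#'
#' @param counts numeric matrix, genes x samples, with gene ids as rownames.
#' @param length_bp named vector of gene lengths in bp (> 0).
#' @param relative logical; return per-sample relative abundances.
#' @return Matrix of normalised abundances, genes x samples.
#' @export
normalize_gene_counts <- function(counts, length_bp, relative = FALSE) {
  counts <- as.matrix(counts)
  len <- length_bp[rownames(counts)]
  if (anyNA(len)) stop("lengths missing for some genes")
  if (any(len <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  x <- counts / (len / 1000)
  if (relative) {
    cs <- colSums(x)
    cs[cs == 0] <- 1
    x <- sweep(x, 2, cs, "/")
  }
  x
}

#' Metagenomic-species abundance from marker genes
#'
#' The abundance of a metagenomic species (MGS) in a sample is the mean of
#' the length-normalised abundances of its marker genes (zeros included in
#' the mean). When fewer than `min_marker_frac` of the markers are detected
#' (raw count > 0) in a sample, the MGS abundance in that sample is set to
#' zero.
#'
#' @param counts raw gene count matrix, genes x samples.
#' @param length_bp named gene lengths (bp).
#' @param catalog named list: MGS id -> character vector of marker gene ids.
#' @param min_marker_frac detection fraction below which the abundance is
#'   nulled (default 0.10, i.e. fewer than 10% of markers found).
#' @param relative logical; normalise samples to relative abundances first.
#' @return Matrix of MGS abundances, samples x MGS (an [abundance_table]-like
#'   orientation for downstream tests).
#' @export
mgs_abundance <- function(counts, length_bp, catalog, min_marker_frac = 0.10,
                          relative = FALSE) {
  if (any(!lengths(catalog))) stop("catalog contains an empty marker list")
  missing <- setdiff(unlist(catalog), rownames(counts))
  if (length(missing)) {
    stop("marker genes absent from the gene matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  norm <- normalize_gene_counts(counts, length_bp, relative = relative)
  out <- matrix(0, ncol(counts), length(catalog),
                dimnames = list(colnames(counts), names(catalog)))
  for (m in names(catalog)) {
    g <- catalog[[m]]
    sub_norm <- norm[g, , drop = FALSE]
    detected <- colMeans(counts[g, , drop = FALSE] > 0)
    ab <- colMeans(sub_norm)
    ab[detected < min_marker_frac] <- 0
    out[, m] <- ab
  }
  out
}

#' Sum MGS abundances at a higher taxonomic rank
#'
#' @param mgs matrix of MGS abundances, samples x MGS.
#' @param lineage data.frame with column `mgs` and one column per rank
#'   (e.g. `genus`).
#' @param rank rank column to roll up to.
#' @return Matrix samples x taxa; per-sample totals are preserved.
#' @export
taxon_rollup <- function(mgs, lineage, rank = "genus") {
  if (!rank %in% names(lineage)) stop("unknown rank: ", rank)
  tax <- lineage[[rank]][match(colnames(mgs), lineage$mgs)]
  if (anyNA(tax)) stop("lineage missing for some MGS")
  t(rowsum(t(mgs), group = tax))
}

#' KEGG-ortholog abundances by summing member genes
#'
#' @param counts raw gene count matrix, genes x samples.
#' @param length_bp named gene lengths (bp).
#' @param gene2ko data.frame with columns `gene`, `ko`; genes without a KO
#'   assignment are skipped.
#' @param relative logical; per-sample relative normalisation first.
#' @return Matrix samples x KO.
#' @export
ko_abundance <- function(counts, length_bp, gene2ko, relative = FALSE) {
  norm <- normalize_gene_counts(counts, length_bp, relative = relative)
  map <- gene2ko[gene2ko$gene %in% rownames(norm) & !is.na(gene2ko$ko), ]
  sub <- norm[map$gene, , drop = FALSE]
  t(rowsum(sub, group = map$ko))
}

#' Cliff's Delta effect size
#'
#' `(#{x_i > y_j} - #{x_i < y_j}) / (n_x * n_y)`, in `[-1, 1]`; positive
#' values mean `x` tends to exceed `y`.
#'
#' @param x,y numeric vectors (non-empty).
#' @return Scalar delta.
#' @export
cliffs_delta <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  # derived from the rank-sum: #greater - #less = 2*U - nx*ny with midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  (2 * u - nx * ny) / (nx * ny)
}

#' Differential abundance between enterotype groups
#'
#' Per feature: a two-sided Wilcoxon-Mann-Whitney test (exact when both
#' groups have at most 8 observations and no ties, otherwise the normal
#' approximation with continuity and tie correction), Benjamini-Hochberg
#' q-values over all tested features, and Cliff's Delta. A feature is
#' reported as enriched in a group when `q < q_max` and `|delta| > cd_min`
#' (PM when delta is positive, i.e. PM values tend to be larger).
#'
#' @param features matrix samples x features (e.g. MGS or KO abundances).
#' @param groups factor/character of "PM"/"RT" per sample (two levels).
#' @param q_max,cd_min significance and effect-size thresholds.
#' @return data.frame with `feature`, `median_pm`, `median_rt`, `p`, `q`,
#'   `delta`, `enriched_in` ("PM", "RT" or "none") and `constant` flag.
#' @export
diff_abundance <- function(features, groups, q_max = 0.1, cd_min = 0.7) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("exactly two groups are required")
  if (min(table(groups)) < 2) stop("need at least 2 samples per group")
  g1 <- which(groups == "PM"); g2 <- which(groups == "RT")
  if (!length(g1) || !length(g2)) { g1 <- which(groups == lv[1]); g2 <- which(groups == lv[2]) }
  res <- lapply(colnames(features), function(f) {
    x <- features[g1, f]; y <- features[g2, f]
    constant <- length(unique(c(x, y))) == 1
    if (constant) {
      p <- 1
    } else {
      exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
      p <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                               correct = TRUE)$p.value)
    }
    data.frame(feature = f, median_pm = stats::median(x), median_rt = stats::median(y),
               p = p, delta = if (constant) 0 else cliffs_delta(x, y),
               constant = constant, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$enriched_in <- ifelse(res$q < q_max & res$delta > cd_min, "PM",
                            ifelse(res$q < q_max & res$delta < -cd_min, "RT", "none"))
  res[, c("feature", "median_pm", "median_rt", "p", "q", "delta",
          "enriched_in", "constant")]
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway with at least one hit, the enrichment p-value is the
#' hypergeometric upper tail `P(X >= k)` with population = the background KO
#' list, successes = pathway KOs within the background, and draws = the hit
#' list.
#'
#' @param hits character vector of significant KOs (subset of `background`).
#' @param background character vector of all tested KOs.
#' @param ko2pathway data.frame with columns `ko`, `pathway`.
#' @param p_max report pathways with `p < p_max`.
#' @return data.frame sorted by ascending p: `pathway`, `k` (hits in
#'   pathway), `K` (background KOs in pathway), `n` (hits), `N`
#'   (background), `p`.
#' @export
enrich_pathways <- function(hits, background, ko2pathway, p_max = 0.05) {
  hits <- unique(hits); background <- unique(background)
  if (!all(hits %in% background)) stop("hits must be a subset of the background")
  map <- ko2pathway[ko2pathway$ko %in% background, ]
  N <- length(background); n <- length(hits)
  out <- lapply(unique(map$pathway), function(pw) {
    kos <- unique(map$ko[map$pathway == pw])
    K <- length(kos)
    k <- length(intersect(kos, hits))
    if (k < 1) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(pathway = character(0), k = integer(0),
                                      K = integer(0), n = integer(0),
                                      N = integer(0), p = numeric(0)))
  out <- out[out$p < p_max, , drop = FALSE]
  out[order(out$p, out$pathway), , drop = FALSE]
}
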