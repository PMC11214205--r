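#' Construct a samples-by-taxa abundance table
#'
#' An `abundance_table` is a non-negative numeric matrix with samples in rows
#' and taxa in columns, tagged as either raw `"counts"` or `"relative"`
#' abundances on the percent scale. Relative tables are expected to have rows
#' summing to 100; tables produced by subsetting taxa (e.g. after
#' [filter_genera()]) may set `partial = TRUE` to relax that check.
#'
#' @param x numeric matrix (samples x taxa) with unique row and column names.
#' @param kind `"counts"` or `"relative"`.
#' @param partial logical; if `TRUE`, skip the row-sum-100 check for relative
#'   tables (used for taxon subsets of a closed composition).
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(x, kind = c("counts", "relative"), partial = FALSE) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("T", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate taxon identifiers")
  if (any(!is.finite(x)) || any(x < 0)) stop("abundances must be finite and non-negative")
  if (kind == "relative" && !partial) {
    rs <- rowSums(x)
    bad <- which(abs(rs - 100) > 1e-6)
    if (length(bad)) {
      stop("relative abundance rows must sum to 100; offending sample(s): ",
           paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
    }
  }
  structure(x, kind = kind, partial = partial, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s%s)\n",
              nrow(x), ncol(x), attr(x, "kind"),
              if (isTRUE(attr(x, "partial"))) ", partial" else ""))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.abundance_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    partial <- isTRUE(attr(x, "partial")) || (!missing(j))
    out <- abundance_table(out, kind = attr(x, "kind"), partial = partial)
  }
  out
}

table_kind <- function(x) attr(x, "kind")

#' Convert a count table to relative abundances (percent)
#'
#' @param table an `abundance_table` of counts.
#' @return An `abundance_table` of kind `"relative"` with rows summing to 100.
#' @export
as_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (identical(table_kind(table), "relative")) return(table)
  rs <- rowSums(table)
  if (any(rs <= 0)) stop("cannot normalise all-zero sample(s): ",
                         paste(rownames(table)[rs <= 0], collapse = ", "))
  abundance_table(100 * unclass(table) / rs, kind = "relative")
}

#' Rarefy a count table to a common sequencing depth
#'
#' Subsamples reads without replacement so that every retained sample has
#' exactly `depth` counts; samples with fewer than `depth` total counts are
#' dropped and listed in the `"dropped"` attribute of the result. The default
#' depth of 7000 counts per sample is the depth used for 16S genus tables in
#' the analyses this package reproduces.
#'
#' @param table an `abundance_table` of counts.
#' @param depth target depth (reads per sample), a positive integer.
#' @param seed integer seed; the subsampling is deterministic given the seed.
#' @return A rarefied `abundance_table` of counts with attribute `"dropped"`
#'   (character vector of removed sample ids).
#' @export
rarefy <- function(table, depth = 7000, seed = 1) {
  stopifnot(inherits(table, "abundance_table"))
  if (!identical(table_kind(table), "counts")) stop("rarefy requires a count table")
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1) stop("depth must be a positive integer")
  rs <- rowSums(table)
  keep <- rs >= depth
  dropped <- rownames(table)[!keep]
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  x <- unclass(table)[keep, , drop = FALSE]
  exact <- rowSums(x) == depth
  if (any(!exact)) {
    set.seed(as.integer(seed))
    # rrarefy's large-count heuristic warning does not apply to genus tables
    x[!exact, ] <- suppressWarnings(
      vegan::rrarefy(x[!exact, , drop = FALSE], sample = depth))
  }
  out <- abundance_table(x, kind = "counts")
  attr(out, "dropped") <- dropped
  out
}

#' Alpha diversity (richness and Shannon index)
#'
#' Richness is the number of taxa present (abundance > 0) in each sample;
#' the Shannon index is computed in nats (natural logarithm) on per-sample
#' proportions.
#'
#' @param table an `abundance_table` (counts or relative).
#' @return A data.frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- unclass(table)
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("all-zero sample(s): ",
                         paste(rownames(x)[rs <= 0], collapse = ", "))
  data.frame(sample_id = rownames(x),
             richness = as.integer(rowSums(x > 0)),
             shannon = as.numeric(vegan::diversity(x, index = "shannon")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sum the sub-genus labels of the selection-target genera
#'
#' The selection criteria aggregate SILVA sub-genus labels: Prevotella as the
#' sum of Prevotella_9, Prevotella_7 and Prevotella; Ruminococcus as the sum
#' of Ruminococcus, Ruminococcus_gnavus_group, Ruminococcus_torques_group and
#' Ruminococcus_gauvreauii_group. Members absent from the table contribute 0
#' (a message lists them).
#'
#' @param table a relative `abundance_table`.
#' @param groups named list mapping composite column name to member taxa.
#' @param replace logical; if `TRUE`, member columns are removed so that row
#'   sums are preserved, otherwise composites are appended.
#' @return An `abundance_table` with the composite columns.
#' @export
aggregate_selection_taxa <- function(table,
                                     groups = list(
                                       Prevotella_sum = c("Prevotella_9", "Prevotella_7", "Prevotella"),
                                       Ruminococcus_sum = c("Ruminococcus", "Ruminococcus_gnavus_group",
                                                            "Ruminococcus_torques_group",
                                                            "Ruminococcus_gauvreauii_group")),
                                     replace = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (!identical(table_kind(table), "relative")) stop("expected a relative abundance table")
  x <- unclass(table)
  members_used <- character(0)
  for (nm in names(groups)) {
    present <- intersect(groups[[nm]], colnames(x))
    missing <- setdiff(groups[[nm]], colnames(x))
    if (length(missing)) {
      message(nm, ": member taxa absent (treated as 0): ", paste(missing, collapse = ", "))
    }
    comp <- if (length(present)) rowSums(x[, present, drop = FALSE]) else rep(0, nrow(x))
    x <- x[, setdiff(colnames(x), nm), drop = FALSE]
    x <- cbind(x, comp)
    colnames(x)[ncol(x)] <- nm
    members_used <- c(members_used, present)
  }
  if (replace) x <- x[, setdiff(colnames(x), members_used), drop = FALSE]
  abundance_table(x, kind = "relative", partial = !replace || isTRUE(attr(table, "partial")))
}

#' Log transform with the standard 0.01 pseudo-count
#'
#' Relative abundances on the percent scale are normalised as
#' `log(x + pseudo)` with a pseudo-count of 0.01 added to remove zeros.
#'
#' @param x numeric vector (or matrix) of non-negative percent abundances.
#' @param pseudo pseudo-count added before taking the natural log.
#' @return `log(x + pseudo)`, same shape as `x`.
#' @export
log_abundance <- function(x, pseudo = 0.01) {
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  log(x + pseudo)
}

#' Filter genera on mean abundance and zero fraction
#'
#' Keeps taxa whose mean relative abundance across samples exceeds
#' `min_mean_pct` percent (the 0.1% rule used for the genetic analyses) and,
#' optionally, whose fraction of zero values is strictly below
#' `max_zero_frac` (the <50%-zeros rule used for the response analysis).
#'
#' @param table a relative `abundance_table`.
#' @param min_mean_pct minimum mean relative abundance in percent (strict >).
#' @param max_zero_frac optional maximum zero fraction in `[0, 1]` (strict <);
#'   `NULL` disables the zero filter.
#' @return A filtered `abundance_table` (marked partial) with attribute
#'   `"n_retained"`.
#' @export
filter_genera <- function(table, min_mean_pct = 0.1, max_zero_frac = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (!identical(table_kind(table), "relative")) stop("expected a relative abundance table")
  if (min_mean_pct < 0 || min_mean_pct > 100) stop("min_mean_pct must be in [0, 100]")
  x <- unclass(table)
  # min_mean_pct = 0 is the identity (a strict > 0 would still drop all-zero taxa)
  keep <- if (min_mean_pct == 0) rep(TRUE, ncol(x)) else colMeans(x) > min_mean_pct
  if (!is.null(max_zero_frac)) {
    if (max_zero_frac < 0 || max_zero_frac > 1) stop("max_zero_frac must be in [0, 1]")
    keep <- keep & (colMeans(x == 0) < max_zero_frac)
  }
  out <- abundance_table(x[, keep, drop = FALSE], kind = "relative", partial = TRUE)
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Read / write abundance tables as TSV
#'
#' The format is one header row of taxon labels, first column `sample_id`.
#'
#' @param path file path.
#' @param kind `"counts"` or `"relative"`.
#' @return `read_abundance_tsv` returns an `abundance_table`.
#' @export
read_abundance_tsv <- function(path, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- as.character(df[[1]])
  abundance_table(x, kind = kind, partial = kind == "relative")
}

#' @rdname read_abundance_tsv
#' @param table an `abundance_table` to write.
#' @export
write_abundance_tsv <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
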