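#' Construct and validate a pedigree
#'
#' A pedigree is a data.frame with at least the columns `animal`, `sire` and
#' `dam` (identifiers; `0` or `NA` marks an unknown parent) and optionally
#' `generation`, `line`, `sex`, `litter` and `batch`. Validation checks that
#' identifiers are unique, that recorded parents are themselves present or
#' unknown, and that the parent-offspring graph is acyclic; records are
#' reordered so that parents precede offspring.
#'
#' @param df data.frame with columns `animal`, `sire`, `dam` (+ optional
#'   metadata columns).
#' @return The validated, parent-first-sorted pedigree with class
#'   `"pedigree"` prepended.
#' @export
pedigree <- function(df) {
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(df))) stop("pedigree needs columns: ", paste(req, collapse = ", "))
  df$animal <- as.character(df$animal)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  df$sire[df$sire %in% c("0", "", NA)] <- NA
  df$dam[df$dam %in% c("0", "", NA)] <- NA
  if (anyDuplicated(df$animal)) stop("duplicate animal identifiers")
  known <- df$animal
  orphan <- setdiff(c(df$sire, df$dam), c(known, NA))
  if (length(orphan)) {
    stop("parents not recorded in the pedigree: ", paste(utils::head(orphan, 5), collapse = ", "))
  }
  df <- sort_pedigree(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

# Kahn topological sort; errors listing a cycle if one exists.
sort_pedigree <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$animal)
  si <- idx[df$sire]; di <- idx[df$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) < n) {
    cyc <- df$animal[setdiff(seq_len(n), order_out)]
    stop("pedigree contains a cycle involving: ", paste(utils::head(cyc, 10), collapse = ", "))
  }
  df[order_out, , drop = FALSE]
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d animals (%d founders)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam))))
  NextMethod()
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds Wright's numerator relationship matrix A with the tabular
#' recursion: `a_ii = 1 + a_{s(i),d(i)}/2` (0 when a parent is unknown) and
#' `a_ij = (a_{j,s(i)} + a_{j,d(i)})/2` for `j` preceding `i` in the
#' parent-first order. Unknown parents are treated as unrelated founders.
#'
#' @param ped a [pedigree()] object (or data.frame coercible to one).
#' @param subjects optional vector of animal ids; the returned matrix is
#'   restricted to these (order preserved).
#' @return Symmetric positive semidefinite relationship matrix with animal
#'   ids as dimnames.
#' @export
a_matrix <- function(ped, subjects = NULL) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row_s <- if (!is.na(s)) A[s, j] else 0
      row_d <- if (!is.na(d)) A[d, j] else 0
      aij <- (row_s + row_d) / 2
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
  }
  if (!is.null(subjects)) {
    subjects <- as.character(subjects)
    miss <- setdiff(subjects, ped$animal)
    if (length(miss)) stop("subjects absent from the pedigree: ", paste(utils::head(miss, 5), collapse = ", "))
    A <- A[subjects, subjects, drop = FALSE]
  }
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' @param ped a [pedigree()] object.
#' @return Named vector of inbreeding coefficients `F = a_ii - 1`.
#' @export
inbreeding <- function(ped) {
  diag(a_matrix(ped)) - 1
}

#' Read a pedigree TSV (columns animal, sire, dam, ...; "0" = unknown parent)
#' @param path file path.
#' @return A [pedigree()] object.
#' @export
read_pedigree_tsv <- function(path) {
  pedigree(utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character"))
}
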