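#' Standardized between-line differences per generation
#'
#' For each feature, fits the fixed-effects model
#' `value ~ sex + generation + generation:batch + generation:line` by
#' ordinary least squares (batch is nested within generation) and extracts
#' the HPM - HRT least-squares-mean contrast within each generation, with
#' its unadjusted t-test p-value and a Tukey (studentized-range) adjusted
#' p-value over all pairwise cell comparisons. Features are standardized to
#' unit variance beforehand (`variant = "standardized"`), so the differences
#' are expressed in standard deviations; `"centered"` additionally centres,
#' `"ranked"` rank-transforms instead.
#'
#' @param data data.frame with columns `line`, `generation`, `sex`, `batch`
#'   and the feature columns.
#' @param features character vector of feature column names.
#' @param variant `"standardized"`, `"centered"` or `"ranked"`.
#' @param baseline line whose mean enters the difference positively
#'   (differences are `baseline - other`).
#' @return A data.frame of class `"response_table"` with columns `feature`,
#'   `generation`, `difference`, `se`, `p_value`, `p_tukey`.
#' @export
line_contrasts <- function(data, features, variant = c("standardized", "centered", "ranked"),
                           baseline = "HPM") {
  variant <- match.arg(variant)
  need <- c("line", "generation", "sex", "batch")
  if (!all(need %in% names(data))) stop("data needs columns: ", paste(need, collapse = ", "))
  df <- data
  df$line <- factor(df$line)
  df$generation <- factor(df$generation)
  df$sex <- factor(df$sex)
  df$batch <- factor(df$batch)
  if (!baseline %in% levels(df$line)) stop("baseline line absent: ", baseline)
  other <- setdiff(levels(df$line), baseline)
  if (length(other) != 1) stop("exactly two lines are required")
  tab <- table(df$line, df$generation)
  if (any(tab == 0)) stop("both lines must be present in every generation")
  # batch re-coded as an index within generation so that generation:batch is
  # the full-rank nested coding
  df$batch_in_gen <- factor(stats::ave(as.integer(df$batch), df$generation,
                                       FUN = function(b) match(b, sort(unique(b)))))
  out <- vector("list", length(features))
  for (k in seq_along(features)) {
    f <- features[k]
    v <- df[[f]]
    if (is.null(v)) stop("feature column absent: ", f)
    v <- switch(variant,
                standardized = v / stats::sd(v),
                centered = as.numeric(scale(v)),
                ranked = rank(v))
    df$.value <- v
    rhs <- if (nlevels(df$batch_in_gen) > 1) {
      .value ~ sex + generation + generation:batch_in_gen + generation:line
    } else .value ~ sex + generation + generation:line
    fit <- stats::lm(rhs, data = df)
    if (anyNA(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; aliased terms: ", paste(bad, collapse = ", "))
    }
    emm <- emmeans::emmeans(fit, ~ line | generation)
    raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
    if (!startsWith(as.character(raw$contrast[1]), baseline)) {
      raw$estimate <- -raw$estimate   # report baseline - other
    }
    emm_all <- emmeans::emmeans(fit, ~ line * generation)
    tuk <- as.data.frame(emmeans::contrast(emm_all, method = "pairwise", adjust = "tukey"))
    gen_levels <- levels(df$generation)
    p_tukey <- vapply(gen_levels, function(g) {
      pat1 <- paste0(baseline, " ", g, " - ", other, " ", g)
      pat2 <- paste0(other, " ", g, " - ", baseline, " ", g)
      hit <- tuk$p.value[tuk$contrast %in% c(pat1, pat2)]
      if (length(hit)) hit[1] else NA_real_
    }, numeric(1))
    out[[k]] <- data.frame(feature = f, generation = gen_levels,
                           difference = raw$estimate, se = raw$SE,
                           p_value = raw$p.value, p_tukey = p_tukey,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("response_table", "data.frame")
  res
}

#' Order features by their G3 between-line difference
#'
#' Reproduces the response-figure ordering: features sorted from the largest
#' positive to the largest negative standardized HPM - HRT difference in the
#' chosen generation; ties are resolved by feature name (stable).
#'
#' @param table a [line_contrasts()] result.
#' @param generation generation whose differences define the order.
#' @return Character vector of feature names in plot order.
#' @export
rank_differences <- function(table, generation = "G3") {
  stopifnot(inherits(table, "data.frame"))
  sub <- table[table$generation == generation, , drop = FALSE]
  if (!nrow(sub)) stop("generation absent from the table: ", generation)
  sub$feature[order(-sub$difference, sub$feature)]
}
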