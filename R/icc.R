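# ANOVA-based intraclass correlation analysis: mean-square decomposition,
# single-rater agreement and consistency ICCs, reproducibility banding and
# the non-parametric between-method comparison.

#' Rating matrix constructor
#'
#' An `n subjects x k raters` matrix of one feature's values.  Raters are
#' observers for inter-observer analysis and sessions for intra-observer
#' analysis.  The design must be complete (no missing cells) with
#' `n >= 2` and `k >= 2`.
#'
#' @param values numeric matrix, subjects in rows, raters in columns.
#' @param feature,method optional labels carried along.
#' @return an object of class `rating_matrix`.
#' @export
rating_matrix <- function(values, feature = NA_character_,
                          method = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("insufficient design: need at least 2 subjects and 2 raters",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("rating matrix must be complete (finite in every cell)",
         call. = FALSE)
  structure(list(values = values, feature = feature, method = method),
            class = "rating_matrix")
}

#' Two-way and one-way ANOVA mean squares of a rating matrix
#'
#' Decomposes the `n x k` matrix into mean squares: `ms_rows` (subjects,
#' `df = n - 1`), `ms_cols` (raters, `df = k - 1`), `ms_error` (two-way
#' residual with interaction folded in, `df = (n-1)(k-1)`) and
#' `ms_within` (one-way within-subject mean square, `df = n(k-1)`).
#' Sums of squares satisfy `SS_total = SS_rows + SS_cols + SS_error` and
#' `SS_total = SS_rows + SS_within`.
#'
#' @param m a [rating_matrix()] or plain numeric matrix.
#' @return an object of class `anova_decomposition`.
#' @export
anova_decompose <- function(m) {
  x <- if (inherits(m, "rating_matrix")) m$values else as.matrix(m)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    stop("insufficient design: need at least 2 subjects and 2 raters",
         call. = FALSE)
  g <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ss_rows <- k * sum((rm_ - g)^2)
  ss_cols <- n * sum((cm - g)^2)
  ss_tot <- sum((x - g)^2)
  ss_within <- sum(sweep(x, 1, rm_)^2)
  ss_err <- max(ss_tot - ss_rows - ss_cols, 0)
  structure(list(
    ms_rows = ss_rows / (n - 1),
    ms_cols = ss_cols / (k - 1),
    ms_error = ss_err / ((n - 1) * (k - 1)),
    ms_within = ss_within / (n * (k - 1)),
    df = c(rows = n - 1, cols = k - 1,
           error = (n - 1) * (k - 1), within = n * (k - 1)),
    n = n, k = k),
    class = "anova_decomposition")
}

icc_result <- function(value, model, n, k,
                       thresholds = c(high = 0.8, medium = 0.5)) {
  structure(list(value = value, model = model,
                 group = if (is.na(value)) NA_character_
                         else classify_icc(value, thresholds),
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.4f  [%s reproducibility; n = %d, k = %d]\n",
              x$model, x$value, x$group, x$n, x$k))
  invisible(x)
}

#' Single-rater agreement ICC, two-way model
#'
#' `ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' the absolute-agreement intraclass correlation of single ratings under
#' a two-way model: rater offsets count against agreement.  Used for
#' inter-observer reproducibility.
#'
#' @param m a [rating_matrix()] or numeric matrix.
#' @param strict if `TRUE` (default) a zero denominator is an error; if
#'   `FALSE` it yields `NA` (callers exclude and log such features).
#' @param thresholds reproducibility band cutoffs, see [classify_icc()].
#' @return an `icc_result` (fields `value`, `model`, `group`, `n`, `k`).
#' @export
icc_agreement <- function(m, strict = TRUE,
                          thresholds = c(high = 0.8, medium = 0.5)) {
  a <- anova_decompose(m)
  num <- a$ms_rows - a$ms_error
  den <- a$ms_rows + (a$k - 1) * a$ms_error +
    (a$k / a$n) * (a$ms_cols - a$ms_error)
  if (abs(den) < 1e-300) {
    if (strict) stop("undefined ICC: zero denominator (no variance)",
                     call. = FALSE)
    return(icc_result(NA_real_, "A-1", a$n, a$k, thresholds))
  }
  icc_result(num / den, "A-1", a$n, a$k, thresholds)
}

#' Single-rater consistency ICC, two-way model
#'
#' `ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)` with `MS_E` the
#' two-way residual mean square, so a constant per-rater offset does not
#' reduce consistency.  Used for intra-observer (session) reproducibility.
#' For a complete two-way layout this is the standard consistency form;
#' the one-way within-subject mean square (`ms_within`) is also exposed
#' by [anova_decompose()] for the one-way (ICC(1,1)) variant.
#'
#' @inheritParams icc_agreement
#' @return an `icc_result`.
#' @export
icc_consistency <- function(m, strict = TRUE,
                            thresholds = c(high = 0.8, medium = 0.5)) {
  a <- anova_decompose(m)
  num <- a$ms_rows - a$ms_error
  den <- a$ms_rows + (a$k - 1) * a$ms_error
  if (abs(den) < 1e-300) {
    if (strict) stop("undefined ICC: zero denominator (no variance)",
                     call. = FALSE)
    return(icc_result(NA_real_, "C-1", a$n, a$k, thresholds))
  }
  icc_result(num / den, "C-1", a$n, a$k, thresholds)
}

#' Reproducibility band of an ICC value
#'
#' `high` for `ICC >= 0.8`, `medium` for `0.5 <= ICC < 0.8`, `low` for
#' `ICC < 0.5` (negative values included).  The three bands partition
#' `(-Inf, 1]` exhaustively and disjointly.
#'
#' @param value ICC value(s), each `<= 1`.
#' @param thresholds named vector with `high` and `medium` cutoffs.
#' @return character vector of band labels.
#' @export
classify_icc <- function(value, thresholds = c(high = 0.8, medium = 0.5)) {
  stopifnot(all(is.na(value) | value <= 1 + 1e-12))
  ifelse(value >= thresholds[["high"]], "high",
         ifelse(value >= thresholds[["medium"]], "medium", "low"))
}

#' Two-sided Wilcoxon rank-sum comparison of two ICC vectors
#'
#' Midranks for ties; exact enumeration when the combined sample size is
#' at most 12 and there are no ties, otherwise the continuity-corrected
#' normal approximation.  When every value is tied across both groups the
#' test is uninformative and `p = 1` by convention.
#'
#' @param icc_a,icc_b numeric vectors (NAs dropped).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration.
#' @return list with `statistic` (the Mann-Whitney U of the first
#'   sample), `p_value` and `method`.
#' @export
wilcoxon_rank_sum <- function(icc_a, icc_b, exact = NULL) {
  a <- icc_a[!is.na(icc_a)]
  b <- icc_b[!is.na(icc_b)]
  if (!length(a) || !length(b))
    stop("both groups must be nonempty", call. = FALSE)
  ties <- any(duplicated(c(a, b)))
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate (all values tied)"))
  }
  if (is.null(exact)) exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method)
}
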