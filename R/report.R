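# Study-level reproducibility summary: per-feature ICCs per segmentation
# method, banding, family summaries and the between-method comparison.

provenance_columns <- function() {
  c("subject", "stage", "tumour_diameter_cm", "method", "observer",
    "session", "volume_path", "mask_path")
}

# Build one n x k rating matrix per feature for a method's sub-table,
# raters ordered by (observer, session).  Errors name missing cells.
method_rating_array <- function(tab, feature_cols) {
  tab <- tab[order(tab$subject, tab$observer, tab$session), , drop = FALSE]
  subjects <- sort(unique(tab$subject))
  raters <- unique(tab[, c("observer", "session")])
  raters <- raters[order(raters$observer, raters$session), , drop = FALSE]
  n <- length(subjects); k <- nrow(raters)
  expected <- merge(data.frame(subject = subjects), raters)
  have <- tab[, c("subject", "observer", "session")]
  key <- function(d) paste(d$subject, d$observer, d$session)
  missing <- setdiff(key(expected), key(have))
  if (length(missing))
    stop("incomplete design: missing (subject, observer, session) cells: ",
         paste(utils::head(missing, 5), collapse = "; "), call. = FALSE)
  if (nrow(tab) != n * k)
    stop("incomplete design: duplicated cells detected", call. = FALSE)
  # rows sorted subject-major, rater-minor: column-fill a k x n matrix
  arr <- lapply(feature_cols, function(fc)
    t(matrix(tab[[fc]], nrow = k, ncol = n)))
  names(arr) <- feature_cols
  list(matrices = arr, n = n, k = k)
}

feature_channel <- function(nm) sub("^([^_]+)_.*$", "\\1", nm)
feature_family <- function(nm) sub("^[^_]+_([^_]+)_.*$", "\\1", nm)

#' Summarize reproducibility of a feature table
#'
#' Builds, for every feature and segmentation method, the subjects x
#' raters rating matrix (raters = all of the method's observer/session
#' combinations jointly) and estimates the single-rater agreement ICC
#' (`ICC(A,1)`).  Features are banded into high / medium / low
#' reproducibility groups, summarized per method and per feature family,
#' and the two methods' per-feature ICC vectors are compared with the
#' two-sided Wilcoxon rank-sum test.  For arms with repeated sessions,
#' per-observer intra-observer consistency ICCs (`ICC(C,1)`, sessions as
#' raters) and per-session inter-observer ICCs are also reported.
#' Features with an undefined ICC (zero denominator) are excluded from
#' summaries and counted in `n_undefined`.
#'
#' @param features data.frame from [extract_study_features()]: provenance
#'   columns plus one column per feature.
#' @param alpha significance level for the method comparison.
#' @param thresholds reproducibility band cutoffs, see [classify_icc()].
#' @return an object of class `reproducibility_report`.
#' @export
summarize_reproducibility <- function(features, alpha = 0.05,
                                      thresholds = c(high = 0.8,
                                                     medium = 0.5)) {
  feature_cols <- setdiff(names(features), provenance_columns())
  if (!length(feature_cols)) stop("no feature columns found", call. = FALSE)
  methods <- setdiff(unique(features$method), "truth")
  icc_tab <- data.frame(feature = feature_cols,
                        channel = feature_channel(feature_cols),
                        family = feature_family(feature_cols),
                        stringsAsFactors = FALSE)
  intra <- list()
  session_sets <- list()
  n_undefined <- stats::setNames(integer(length(methods)), methods)
  for (m in methods) {
    tab <- features[features$method == m, , drop = FALSE]
    ra <- method_rating_array(tab, feature_cols)
    vals <- vapply(feature_cols, function(fc) {
      icc_agreement(ra$matrices[[fc]], strict = FALSE,
                    thresholds = thresholds)$value
    }, numeric(1))
    n_undefined[m] <- sum(is.na(vals))
    icc_tab[[paste0("icc_", m)]] <- vals
    icc_tab[[paste0("group_", m)]] <-
      ifelse(is.na(vals), NA_character_, classify_icc(vals, thresholds))
    # intra-observer: sessions as raters, per observer
    sessions <- sort(unique(tab$session))
    observers <- sort(unique(tab$observer))
    if (length(sessions) >= 2) {
      for (obs in observers) {
        sub <- tab[tab$observer == obs, , drop = FALSE]
        sub$observer <- sub$session  # sessions become the rater axis
        sub$session <- 1L
        ras <- method_rating_array(sub, feature_cols)
        v <- vapply(feature_cols, function(fc)
          icc_consistency(ras$matrices[[fc]], strict = FALSE,
                          thresholds = thresholds)$value, numeric(1))
        intra[[paste0(m, "_obs", obs)]] <- data.frame(
          method = m, observer = obs,
          mean_icc = mean(v, na.rm = TRUE),
          sd_icc = stats::sd(v, na.rm = TRUE),
          n_undefined = sum(is.na(v)))
      }
      if (length(observers) >= 2) {
        for (sess in sessions) {
          sub <- tab[tab$session == sess, , drop = FALSE]
          ras <- method_rating_array(sub, feature_cols)
          v <- vapply(feature_cols, function(fc)
            icc_agreement(ras$matrices[[fc]], strict = FALSE,
                          thresholds = thresholds)$value, numeric(1))
          session_sets[[paste0(m, "_sess", sess)]] <- data.frame(
            method = m, session = sess,
            mean_icc = mean(v, na.rm = TRUE),
            sd_icc = stats::sd(v, na.rm = TRUE))
        }
      }
    }
  }
  method_summary <- do.call(rbind, lapply(methods, function(m) {
    v <- icc_tab[[paste0("icc_", m)]]
    data.frame(method = m, mean_icc = mean(v, na.rm = TRUE),
               sd_icc = stats::sd(v, na.rm = TRUE),
               n_features = sum(!is.na(v)),
               n_undefined = n_undefined[[m]], row.names = NULL)
  }))
  family_summary <- do.call(rbind, lapply(methods, function(m) {
    v <- icc_tab[[paste0("icc_", m)]]
    do.call(rbind, lapply(split(seq_along(v), icc_tab$family), function(ii)
      data.frame(method = m, family = icc_tab$family[ii[1]],
                 mean_icc = mean(v[ii], na.rm = TRUE),
                 sd_icc = stats::sd(v[ii], na.rm = TRUE),
                 n_features = length(ii), row.names = NULL)))
  }))
  group_levels <- c("high", "medium", "low")
  group_counts <- do.call(rbind, lapply(methods, function(m) {
    gr <- icc_tab[[paste0("group_", m)]]
    gr <- gr[!is.na(gr)]
    cnt <- vapply(group_levels, function(g) sum(gr == g), integer(1))
    data.frame(method = m, group = group_levels, count = cnt,
               pct = 100 * cnt / max(length(gr), 1), row.names = NULL)
  }))
  comparison <- NULL
  if (all(c("manual", "semiauto") %in% methods)) {
    keep <- !is.na(icc_tab$icc_semiauto) & !is.na(icc_tab$icc_manual)
    wt <- wilcoxon_rank_sum(icc_tab$icc_semiauto[keep],
                            icc_tab$icc_manual[keep])
    comparison <- c(wt, list(alpha = alpha,
                             significant = wt$p_value < alpha,
                             direction = if (mean(icc_tab$icc_semiauto[keep]) >
                                             mean(icc_tab$icc_manual[keep]))
                               "semiauto > manual" else "manual >= semiauto"))
  }
  structure(list(
    per_feature = icc_tab,
    method_summary = method_summary,
    family_summary = family_summary,
    group_counts = group_counts,
    comparison = comparison,
    intra_observer = if (length(intra)) do.call(rbind, intra) else NULL,
    session_sets = if (length(session_sets)) do.call(rbind, session_sets)
                   else NULL,
    alpha = alpha, thresholds = thresholds,
    n_features = length(feature_cols)),
    class = "reproducibility_report")
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat("Reproducibility report (", x$n_features, " features)\n\n", sep = "")
  ms <- x$method_summary
  for (i in seq_len(nrow(ms)))
    cat(sprintf("  %-9s mean ICC = %.3f +/- %.3f (%d features, %d undefined)\n",
                ms$method[i], ms$mean_icc[i], ms$sd_icc[i],
                ms$n_features[i], ms$n_undefined[i]))
  cat("\n  Reproducibility groups:\n")
  for (m in unique(x$group_counts$method)) {
    g <- x$group_counts[x$group_counts$method == m, ]
    cat(sprintf("    %-9s %s\n", m,
                paste(sprintf("%s %d (%.1f%%)", g$group, g$count, g$pct),
                      collapse = ", ")))
  }
  if (!is.null(x$comparison))
    cat(sprintf("\n  Wilcoxon rank-sum (semiauto vs manual): W = %.1f, p = %.3g (%s)\n",
                x$comparison$statistic, x$comparison$p_value,
                x$comparison$direction))
  invisible(x)
}

#' Write a reproducibility report to disk
#'
#' Writes a versioned JSON document and, optionally, a human-readable
#' Markdown summary whose banding table mirrors the layout
#' group x method with counts and percentages.
#'
#' @param report a [summarize_reproducibility()] result.
#' @param json_path output path for the JSON document.
#' @param md_path optional output path for the Markdown summary.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  payload <- unclass(report)
  payload$schema_version <- "1.0"
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(md_path)) {
    ms <- report$method_summary
    methods <- unique(report$group_counts$method)
    header <- paste0("| Group | ", paste(methods, collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---|", length(methods) + 1), collapse = ""))
    body <- vapply(c("high", "medium", "low"), function(g) {
      cells <- vapply(methods, function(m) {
        r <- report$group_counts[report$group_counts$method == m &
                                 report$group_counts$group == g, ]
        sprintf("%d (%.1f%%)", r$count, r$pct)
      }, character(1))
      paste0("| ", g, " | ", paste(cells, collapse = " | "), " |")
    }, character(1))
    lines <- c(
      "# Reproducibility report", "",
      sprintf("- **%s**: mean ICC = %.3f +/- %.3f (n = %d)",
              ms$method, ms$mean_icc, ms$sd_icc, ms$n_features),
      "", header, rule, body)
    if (!is.null(report$comparison))
      lines <- c(lines, "",
                 sprintf("Wilcoxon rank-sum (semiauto vs manual): W = %.1f, p = %.4g",
                         report$comparison$statistic,
                         report$comparison$p_value))
    writeLines(lines, md_path)
  }
  invisible(json_path)
}
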