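# End-to-end orchestration: generate/load study -> segment -> extract ->
# analyze -> report, with deterministic on-disk artifacts.

#' Pipeline configuration
#'
#' A single serializable object holding the study design, the feature
#' extraction settings and the analysis options.  `pipeline_config_json()`
#' round-trips the configuration through a JSON document; unknown keys
#' are rejected so that typos fail loudly.
#'
#' @param design a [study_design()].
#' @param features a [feature_config()].
#' @param alpha significance level for the method comparison.
#' @param thresholds reproducibility band cutoffs.
#' @param out_dir output directory (`NULL` = keep everything in memory).
#' @param persist_images whether to write NIfTI volumes and masks (the
#'   feature table and report are always written when `out_dir` is set).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(design = study_design(),
                            features = feature_config(),
                            alpha = 0.05,
                            thresholds = c(high = 0.8, medium = 0.5),
                            out_dir = NULL, persist_images = FALSE) {
  stopifnot(inherits(design, "study_design"),
            inherits(features, "feature_config"))
  structure(list(design = design, features = features, alpha = alpha,
                 thresholds = thresholds, out_dir = out_dir,
                 persist_images = persist_images),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file to read or write.
#' @param config (writing) a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(
    list(design = unclass(config$design),
         features = unclass(config$features),
         alpha = config$alpha,
         thresholds = as.list(config$thresholds),
         out_dir = config$out_dir,
         persist_images = config$persist_images),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("design", "features", "alpha", "thresholds", "out_dir",
             "persist_images")
  bad <- setdiff(names(doc), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  check_keys <- function(given, fn, what) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad))
      stop("unknown ", what, " keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    given
  }
  design <- do.call(study_design,
                    check_keys(doc$design %||% list(), study_design,
                               "design"))
  features <- do.call(feature_config,
                      check_keys(doc$features %||% list(), feature_config,
                                 "features"))
  thresholds <- if (is.null(doc$thresholds)) c(high = 0.8, medium = 0.5)
                else unlist(doc$thresholds)
  pipeline_config(design = design, features = features,
                  alpha = doc$alpha %||% 0.05, thresholds = thresholds,
                  out_dir = doc$out_dir,
                  persist_images = isTRUE(doc$persist_images))
}

#' Extract features for every mask of a study
#'
#' Runs [extract_all()] on each (volume, mask) pair and returns one row
#' per mask: the provenance columns of the study manifest followed by the
#' named feature columns.
#'
#' @param study a [generate_study()] result.
#' @param config a [feature_config()].
#' @return data.frame (provenance + one column per feature).
#' @export
extract_study_features <- function(study, config = feature_config()) {
  stopifnot(inherits(study, "radiomic_study"))
  rows <- vector("list", length(study$masks))
  for (i in seq_along(study$masks)) {
    mask <- study$masks[[i]]
    subj <- mask$provenance$subject
    fv <- extract_all(study$phantoms[[subj]]$volume, mask, config)
    rows[[i]] <- c(as.list(study$manifest[i, , drop = FALSE]),
                   as.list(unclass(fv)))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read and write feature tables
#'
#' CSV round-trip at full double precision (`%.17g`), with stable column
#' order, so identical studies yield byte-identical files.
#'
#' @param features data.frame from [extract_study_features()].
#' @param path CSV file path.
#' @return the reader returns the data.frame; the writer the path,
#'   invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the full reproducibility pipeline
#'
#' Generates the synthetic study, extracts the full feature vector for
#' every mask, runs the ICC analysis and (when `out_dir` is set) persists
#' the feature table (`features.csv`), the report (`report.json`,
#' `report.md`) and optionally all images.  Fully reproducible: the same
#' configuration and seed give byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return the [summarize_reproducibility()] report, with the feature
#'   table attached as attribute `"features"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(
    config$design,
    dir = if (!is.null(out_dir) && config$persist_images)
      file.path(out_dir, "study") else NULL)
  features <- extract_study_features(study, config$features)
  if (!is.null(out_dir))
    write_feature_table(features, file.path(out_dir, "features.csv"))
  report <- summarize_reproducibility(features, alpha = config$alpha,
                                      thresholds = config$thresholds)
  if (!is.null(out_dir))
    write_report(report, file.path(out_dir, "report.json"),
                 file.path(out_dir, "report.md"))
  attr(report, "features") <- features
  report
}
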