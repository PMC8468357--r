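#' Feature extraction configuration
#'
#' Collects the tunable parameters of the 662-feature extractor.
#'
#' @param bins bin count for `fixed-bin-count` discretization (or the bin
#'   width under `fixed-bin-width`); every channel is re-discretized
#'   independently on its own masked intensity range.
#' @param bin_policy discretization policy, see [discretize()].
#' @param glcm_distance co-occurrence offset magnitude in voxels.
#' @param gldm_alpha gray-level similarity cutoff for dependence counting.
#' @param gldm_delta Chebyshev neighbourhood radius for dependence counting.
#' @param channels character vector of channels to compute intensity and
#'   texture features on; `"original"` plus any of the eight wavelet
#'   labels.
#' @param families feature families to compute (subset of
#'   [all_families()]); shape, when included, is computed on the original
#'   geometry only.
#' @param eps numerical guard constant used inside entropy logarithms.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(bins = 32, bin_policy = "fixed-bin-count",
                           glcm_distance = 1L, gldm_alpha = 0,
                           gldm_delta = 1L,
                           channels = all_channels(),
                           families = all_families(),
                           eps = 2.2e-16) {
  bad <- setdiff(channels, all_channels())
  if (length(bad))
    stop("unknown channels: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(families, all_families())
  if (length(bad))
    stop("unknown families: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(bins = bins, bin_policy = bin_policy,
                 glcm_distance = as.integer(glcm_distance),
                 gldm_alpha = gldm_alpha,
                 gldm_delta = as.integer(gldm_delta),
                 channels = channels, families = families, eps = eps),
            class = "feature_config")
}

#' @rdname feature_config
#' @export
all_families <- function() {
  c("shape", "firstorder", "glcm", "glrlm", "gldm")
}

#' @rdname feature_config
#' @export
all_channels <- function() {
  c("original", paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                                     "HLL", "HLH", "HHL", "HHH")))
}

#' Names of the full feature vector
#'
#' @param config a [feature_config()].
#' @return character vector of `<channel>_<family>_<feature>` names; 662
#'   entries under the default configuration (14 shape + 9 channels x
#'   (18 first-order + 24 GLCM + 16 GLRLM + 14 GLDM)).
#' @export
feature_names <- function(config = feature_config()) {
  fo <- c("InterquartileRange", "Skewness", "Uniformity", "Median", "Energy",
          "RobustMeanAbsoluteDeviation", "MeanAbsoluteDeviation",
          "TotalEnergy", "Maximum", "RootMeanSquared", "Percentile90",
          "Minimum", "Entropy", "Range", "Variance", "Percentile10",
          "Kurtosis", "Mean")
  gl <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
          "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
          "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
          "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
          "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
          "SumAverage", "SumEntropy", "SumSquares")
  rl <- c("ShortRunLowGrayLevelEmphasis", "GrayLevelVariance",
          "LowGrayLevelRunEmphasis", "GrayLevelNonUniformityNormalized",
          "RunVariance", "GrayLevelNonUniformity", "LongRunEmphasis",
          "ShortRunHighGrayLevelEmphasis", "RunLengthNonUniformity",
          "ShortRunEmphasis", "LongRunHighGrayLevelEmphasis",
          "RunPercentage", "LongRunLowGrayLevelEmphasis", "RunEntropy",
          "HighGrayLevelRunEmphasis", "RunLengthNonUniformityNormalized")
  dm <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
          "GrayLevelNonUniformity", "DependenceNonUniformity",
          "DependenceNonUniformityNormalized", "GrayLevelVariance",
          "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
          "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
          "SmallDependenceHighGrayLevelEmphasis",
          "LargeDependenceLowGrayLevelEmphasis",
          "LargeDependenceHighGrayLevelEmphasis")
  sh <- c("VoxelVolume", "Maximum3DDiameter", "MeshVolume",
          "MajorAxisLength", "Sphericity", "LeastAxisLength", "Elongation",
          "SurfaceVolumeRatio", "Maximum2DDiameterSlice", "Flatness",
          "SurfaceArea", "MinorAxisLength", "Maximum2DDiameterColumn",
          "Maximum2DDiameterRow")
  fam <- config$families
  out <- if ("shape" %in% fam) paste0("original_shape_", sh) else character(0)
  for (ch in config$channels) {
    if ("firstorder" %in% fam) out <- c(out, paste0(ch, "_firstorder_", fo))
    if ("glcm" %in% fam) out <- c(out, paste0(ch, "_glcm_", gl))
    if ("glrlm" %in% fam) out <- c(out, paste0(ch, "_glrlm_", rl))
    if ("gldm" %in% fam) out <- c(out, paste0(ch, "_gldm_", dm))
  }
  out
}

#' Extract the full radiomic feature vector
#'
#' Computes shape features (original geometry only) plus first-order and
#' texture (GLCM, GLRLM, GLDM) features on the original image and on each
#' of the eight undecimated wavelet channels:
#' 14 + 9 x 72 = 662 named values under the default configuration.
#' Filtering and feature computation run on a bounding-box crop around
#' the mask (padded beyond the wavelet filter support), which leaves all
#' features unchanged relative to full-volume computation because every
#' feature only reads masked voxels.
#'
#' @param volume a [volume3d()].
#' @param mask an aligned [segmentation_mask()].
#' @param config a [feature_config()].
#' @return named numeric vector (class `feature_vector`), in the order of
#'   [feature_names()].
#' @export
extract_all <- function(volume, mask, config = feature_config()) {
  stopifnot(inherits(volume, "volume3d"), inherits(mask, "segmentation_mask"))
  check_alignment(volume, mask)
  if (!any(mask$data)) stop("empty mask", call. = FALSE)
  spacing <- volume$spacing
  vv <- prod(spacing)
  bb <- mask_bbox(mask$data, pad = 4L)  # beyond the wavelet filter radius
  img <- crop_bbox(volume$intensities, bb)
  msk <- crop_bbox(mask$data, bb)
  fam <- config$families
  out <- numeric(0)
  if ("shape" %in% fam) {
    sub_mask <- segmentation_mask(msk, spacing = spacing,
                                  method = mask$provenance$method)
    out <- shape_features(sub_mask, spacing)
    names(out) <- paste0("original_shape_", names(out))
  }
  need_wavelet <- any(grepl("^wavelet-", config$channels))
  wl <- if (need_wavelet) wavelet_decompose(img) else NULL
  # texture and first-order statistics only read masked voxels, so work on
  # the tight bounding box of the mask within the padded crop
  bbt <- mask_bbox(msk, pad = 0L)
  msk_t <- crop_bbox(msk, bbt)
  rl_geom <- glrlm_geometry(msk_t)  # mask-only; shared by all channels
  for (ch in config$channels) {
    arr <- if (ch == "original") img else wl[[sub("wavelet-", "", ch)]]
    arr <- crop_bbox(arr, bbt)
    msk <- msk_t
    disc <- discretize(arr, msk, policy = config$bin_policy,
                       parameter = config$bins)
    vals <- arr[msk]
    fo <- if ("firstorder" %in% fam)
      first_order_features(vals, disc, voxel_volume = vv,
                           eps = config$eps) else numeric(0)
    gc_ <- if ("glcm" %in% fam)
      glcm_features(glcm(disc, distance = config$glcm_distance),
                    eps = config$eps) else numeric(0)
    rl <- if ("glrlm" %in% fam)
      glrlm_features(glrlm(disc, geom = rl_geom), eps = config$eps)
      else numeric(0)
    dm <- if ("gldm" %in% fam)
      gldm_features(gldm(disc, alpha = config$gldm_alpha,
                         delta = config$gldm_delta), eps = config$eps)
      else numeric(0)
    block <- c(fo, gc_, rl, dm)
    names(block) <- paste0(ch, "_",
                           rep(c("firstorder", "glcm", "glrlm", "gldm"),
                               times = c(length(fo), length(gc_),
                                         length(rl), length(dm))),
                           "_", names(block))
    out <- c(out, block)
  }
  expected <- feature_names(config)
  stopifnot(identical(names(out), expected))
  class(out) <- c("feature_vector", class(out))
  out
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %d features across %d channels\n",
              length(x), length(unique(sub("_.*$", "", names(x))))))
  fam <- sub("^[^_]+_([^_]+)_.*$", "\\1", names(x))
  print(table(fam))
  invisible(x)
}
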