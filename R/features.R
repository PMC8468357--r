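# Radiomic feature families: first-order statistics and the texture-matrix
# feature sets.  Formula conventions (percentile interpolation, population
# moments, degenerate-case values) are documented per feature family below;
# texture values additionally depend on the discretization settings.

#' First-order (intensity histogram) features
#'
#' The 18 first-order features of the extractor: Interquartile Range,
#' Skewness, Uniformity, Median, Energy, Robust Mean Absolute Deviation,
#' Mean Absolute Deviation, Total Energy, Maximum, Root Mean Squared,
#' 90th Percentile, Minimum, Entropy, Range, Variance, 10th Percentile,
#' Kurtosis, Mean.
#'
#' Conventions: percentiles use linear interpolation between order
#' statistics (R `quantile()` type 7); Variance and the moment ratios use
#' population (divide-by-N) moments; Kurtosis is non-excess (Pearson), so
#' a Gaussian sample gives about 3; Skewness/Kurtosis of a constant region
#' are 0; Entropy and Uniformity are computed from the discretized
#' histogram with probabilities `p(i)` and guard constant `eps`
#' (`Entropy = -sum p log2(p + eps)`, `Uniformity = sum p^2`); Total
#' Energy multiplies Energy by the physical voxel volume in mm^3.
#'
#' @param values numeric vector of masked voxel intensities.
#' @param disc the [discretize()]d channel (for Entropy/Uniformity).
#' @param voxel_volume physical voxel volume in mm^3.
#' @param eps numerical guard used inside the entropy logarithm.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(values, disc, voxel_volume = 1,
                                 eps = 2.2e-16) {
  if (!length(values)) stop("empty mask", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  q <- stats::quantile(values, c(0.10, 0.25, 0.5, 0.75, 0.90),
                       names = FALSE, type = 7)
  inner <- values[values >= q[1] & values <= q[5]]
  lvls <- disc$levels[!is.na(disc$levels)]
  p <- tabulate(lvls, nbins = disc$n_levels)
  p <- p / sum(p)
  energy <- sum(values^2)
  c(
    InterquartileRange = q[4] - q[2],
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Uniformity = sum(p^2),
    Median = q[3],
    Energy = energy,
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    MeanAbsoluteDeviation = mean(abs(values - m)),
    TotalEnergy = voxel_volume * energy,
    Maximum = max(values),
    RootMeanSquared = sqrt(energy / n),
    Percentile90 = q[5],
    Minimum = min(values),
    Entropy = -sum(p * log2(p + eps)),
    Range = max(values) - min(values),
    Variance = m2,
    Percentile10 = q[1],
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Mean = m
  )
}

#' Gray-level co-occurrence matrix features
#'
#' The 24 GLCM features, computed from the direction-averaged normalized
#' matrix `p(i, j)` and its marginals.  Degenerate conventions: when a
#' marginal standard deviation is zero (single occupied level),
#' Correlation and MCC return 1 (the perfectly-dependent limit); Imc1
#' returns 0 when `max(HX, HY) = 0`; the Imc2 radicand is clamped at 0.
#'
#' @param g a [glcm()] result.
#' @param eps numerical guard for logarithms.
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(g, eps = 2.2e-16) {
  stopifnot(inherits(g, "glcm_matrix"))
  p <- g$p
  ng <- g$n_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) marginals
  kdiff <- 0:(ng - 1)
  pdiff <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  ksum <- 2:(2 * ng)
  psum <- vapply(ksum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(kdiff * pdiff)
  hx <- -sum(px * log2(px + eps))
  hy <- -sum(py * log2(py + eps))
  hxy <- -sum(p * log2(p + eps))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2(pxy + eps))
  hxy2 <- -sum(pxy * log2(pxy + eps))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sx > 0 && sy > 0) (sum(i * j * p) - mux * muy) / (sx * sy) else 1
  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pdiff * log2(pdiff + eps)),
    DifferenceVariance = sum((kdiff - da)^2 * pdiff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j)^2 / ng^2))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = glcm_mcc(p, px, py),
    MaximumProbability = max(p),
    SumAverage = sum(ksum * psum),
    SumEntropy = -sum(psum * log2(psum + eps)),
    SumSquares = sum((i - mux)^2 * p)
  )
}

# Maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(a, b) = sum_k p(a, k) p(b, k) / (px(a) py(k)), restricted to occupied
# levels.  A single occupied level returns 1 by convention.
glcm_mcc <- function(p, px, py) {
  keep <- px > 0
  keepc <- py > 0
  if (sum(keep) < 2 || sum(keepc) < 2) return(1)
  ps <- p[keep, keepc, drop = FALSE]
  pxs <- px[keep]; pys <- py[keepc]
  q <- (ps / pxs) %*% t(sweep(ps, 2, pys, "/"))
  ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2) return(1)
  sqrt(max(ev[2], 0))
}

#' Gray-level run-length matrix features
#'
#' The 16 GLRLM features, computed from the aggregate run-count matrix
#' (runs summed over the 13 directions).  `Nr` is the total run count and
#' `Np` the voxel total `sum l * r(i, l)` (the masked voxel count times
#' the number of directions), so Run Percentage is `Nr / Np`.
#'
#' @param g a [glrlm()] result.
#' @param eps numerical guard for logarithms.
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(g, eps = 2.2e-16) {
  stopifnot(inherits(g, "glrlm_matrix"))
  r <- g$counts
  ng <- nrow(r); nl <- ncol(r)
  i <- matrix(seq_len(ng), ng, nl)
  l <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  nr <- sum(r)
  if (nr == 0) stop("degenerate matrix: no runs", call. = FALSE)
  np <- sum(l * r)
  pr <- r / nr
  ri <- rowSums(r); rl <- colSums(r)
  mu_i <- sum(pr * i); mu_l <- sum(pr * l)
  iv <- seq_len(ng); lv <- seq_len(nl)
  c(
    ShortRunLowGrayLevelEmphasis = sum(r / (i^2 * l^2)) / nr,
    GrayLevelVariance = sum(pr * (i - mu_i)^2),
    LowGrayLevelRunEmphasis = sum(ri / iv^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunVariance = sum(pr * (l - mu_l)^2),
    GrayLevelNonUniformity = sum(ri^2) / nr,
    LongRunEmphasis = sum(rl * lv^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(r * i^2 / l^2) / nr,
    RunLengthNonUniformity = sum(rl^2) / nr,
    ShortRunEmphasis = sum(rl / lv^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(r * i^2 * l^2) / nr,
    RunPercentage = nr / np,
    LongRunLowGrayLevelEmphasis = sum(r * l^2 / i^2) / nr,
    RunEntropy = -sum(pr * log2(pr + eps)),
    HighGrayLevelRunEmphasis = sum(ri * iv^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / nr^2
  )
}

#' Gray-level dependence matrix features
#'
#' The 14 GLDM features.  In the formulas, the dependence index `j` runs
#' from 1, with `j = dependence count + 1` (a voxel with no dependent
#' neighbours sits in column 1); this offset keeps the small-dependence
#' emphases finite.  `Nz` equals the number of masked voxels.
#'
#' @param g a [gldm()] result.
#' @param eps numerical guard for logarithms.
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(g, eps = 2.2e-16) {
  stopifnot(inherits(g, "gldm_matrix"))
  d <- g$counts
  ng <- nrow(d); nd <- ncol(d)
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE)
  nz <- sum(d)
  pd <- d / nz
  di <- rowSums(d); dj <- colSums(d)
  iv <- seq_len(ng); jv <- seq_len(nd)
  mu_i <- sum(pd * i); mu_j <- sum(pd * j)
  c(
    SmallDependenceEmphasis = sum(dj / jv^2) / nz,
    LargeDependenceEmphasis = sum(dj * jv^2) / nz,
    GrayLevelNonUniformity = sum(di^2) / nz,
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    GrayLevelVariance = sum(pd * (i - mu_i)^2),
    DependenceVariance = sum(pd * (j - mu_j)^2),
    DependenceEntropy = -sum(pd * log2(pd + eps)),
    LowGrayLevelEmphasis = sum(di / iv^2) / nz,
    HighGrayLevelEmphasis = sum(di * iv^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(d / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(d * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(d * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(d * i^2 * j^2) / nz
  )
}
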