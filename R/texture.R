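#' Gray-level discretization of a masked volume
#'
#' Maps masked voxel intensities to integer gray levels `1..N`.  Two
#' policies are supported.  `fixed-bin-count` divides the masked intensity
#' range `[min, max]` into `parameter` equal bins (the default used by the
#' feature extractor; texture values depend on this choice, so it is
#' explicit and configurable).  `fixed-bin-width` assigns
#' `level = floor((I - min) / parameter) + 1`.  A constant region yields a
#' single level.
#'
#' @param volume a [volume3d()] (or a bare 3D array).
#' @param mask a [segmentation_mask()] (or logical array) on the same grid.
#' @param policy `"fixed-bin-count"` or `"fixed-bin-width"`.
#' @param parameter bin count (>= 1) or bin width (> 0).
#' @return an object of class `discretized_volume` with fields `levels`
#'   (integer array, `NA` outside the mask), `ng` (number of occupied
#'   bins), `n_levels` (highest level index), `edges`, `policy`.
#' @export
discretize <- function(volume, mask,
                       policy = c("fixed-bin-count", "fixed-bin-width"),
                       parameter = 32) {
  policy <- match.arg(policy)
  v <- if (inherits(volume, "volume3d")) volume$intensities else volume
  m <- if (inherits(mask, "segmentation_mask")) mask$data else mask
  stopifnot(identical(dim(v), dim(m)))
  if (!any(m)) stop("empty mask", call. = FALSE)
  vals <- v[m]
  lo <- min(vals); hi <- max(vals)
  levels <- array(NA_integer_, dim(v))
  if (policy == "fixed-bin-count") {
    nbins <- as.integer(parameter)
    if (nbins < 1L) stop("bin count must be >= 1", call. = FALSE)
    if (hi == lo) {
      levels[m] <- 1L
      edges <- c(lo, hi)
    } else {
      w <- (hi - lo) / nbins
      lv <- pmin(floor((vals - lo) / w) + 1, nbins)
      levels[m] <- as.integer(lv)
      edges <- lo + w * (0:nbins)
    }
  } else {
    w <- as.numeric(parameter)
    if (w <= 0) stop("bin width must be > 0", call. = FALSE)
    lv <- floor((vals - lo) / w) + 1
    levels[m] <- as.integer(lv)
    edges <- lo + w * (0:max(lv))
  }
  n_levels <- max(levels, na.rm = TRUE)
  structure(
    list(levels = levels, mask = m, ng = length(unique(levels[m])),
         n_levels = as.integer(n_levels), edges = edges, policy = policy),
    class = "discretized_volume")
}

#' @export
print.discretized_volume <- function(x, ...) {
  cat(sprintf("<discretized_volume> %s, %d occupied of %d levels, %d voxels\n",
              x$policy, x$ng, x$n_levels, sum(x$mask)))
  invisible(x)
}

#' The 13 unique direction offsets at unit Chebyshev distance in 3D
#'
#' The 26 neighbours of a voxel come in 13 antipodal pairs; one
#' representative per pair (the one whose first nonzero component is
#' positive in `(x, y, z)` precedence) is enumerated in a fixed order.
#'
#' @return a 13 x 3 integer matrix of `(dx, dy, dz)` offsets.
#' @export
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first_nonzero_sign <- apply(g, 1, function(r) r[which(r != 0)[1]])
  out <- unname(g[first_nonzero_sign > 0, , drop = FALSE])
  out[order(out[, 3], out[, 2], out[, 1]), , drop = FALSE]
}

#' Gray-level co-occurrence matrix
#'
#' Counts symmetric co-occurrences of gray-level pairs among masked voxels
#' separated by `distance` voxels along each direction.  Each direction's
#' count matrix is made symmetric (both orderings of the pair counted),
#' normalized to sum 1, and the normalized matrices are averaged over the
#' 13 unique 3D directions.  Only voxel pairs that both lie inside the
#' mask are counted.  Direction offsets are in voxel lattice units;
#' anisotropic spacing is ignored, matching common practice.
#'
#' @param disc a [discretize()]d volume.
#' @param distance voxel offset magnitude (default 1).
#' @param directions integer matrix of direction offsets; defaults to
#'   [texture_directions()].
#' @return an object of class `glcm_matrix`: `p` (averaged normalized
#'   matrix), `per_direction` (list of normalized per-direction matrices),
#'   `counts_per_direction`, `n_levels`.
#' @export
glcm <- function(disc, distance = 1L, directions = texture_directions()) {
  stopifnot(inherits(disc, "discretized_volume"), distance >= 1)
  ng <- disc$n_levels
  lv <- sentinel_levels(disc)
  dims <- dim(lv)
  per_counts <- vector("list", nrow(directions))
  per_p <- vector("list", nrow(directions))
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ] * as.integer(distance)
    cnt <- offset_pair_counts(lv, dims, d, ng)
    cnt <- cnt + t(cnt)  # symmetric co-occurrence
    per_counts[[r]] <- cnt
    s <- sum(cnt)
    per_p[[r]] <- if (s > 0) cnt / s else cnt
  }
  tot <- Reduce(`+`, lapply(per_counts, sum))
  if (tot == 0)
    stop("degenerate matrix: no valid voxel pair in any direction",
         call. = FALSE)
  # directions with no pairs contribute a zero matrix; average over the
  # directions that produced pairs
  has <- vapply(per_counts, function(m) sum(m) > 0, logical(1))
  p <- Reduce(`+`, per_p[has]) / sum(has)
  structure(list(p = p, per_direction = per_p,
                 counts_per_direction = per_counts,
                 n_levels = ng, directions = directions),
            class = "glcm_matrix")
}

# Levels with NA (outside the mask) replaced by a large negative sentinel:
# pair indices involving it fall outside 1..nbins and are silently dropped
# by tabulate(), and |a - b| <= alpha is never true against a real level.
sentinel_levels <- function(disc) {
  lv <- disc$levels
  lv[is.na(lv)] <- -1048576L
  lv
}

# valid index range along one axis for an offset component; NULL if empty
offset_range <- function(n, dc) {
  lo <- max(1L, 1L - dc); hi <- min(n, n - dc)
  if (lo > hi) NULL else lo:hi
}

# count ordered co-occurrences (i at v, j at v + d) for one offset
offset_pair_counts <- function(lv, dims, d, ng) {
  rx <- offset_range(dims[1], d[1])
  ry <- offset_range(dims[2], d[2])
  rz <- offset_range(dims[3], d[3])
  if (is.null(rx) || is.null(ry) || is.null(rz))
    return(matrix(0, ng, ng))
  a <- lv[rx, ry, rz, drop = FALSE]
  b <- lv[rx + d[1], ry + d[2], rz + d[3], drop = FALSE]
  # sentinel pairs index far outside 1..ng^2 and are dropped by tabulate
  matrix(tabulate((a + ng * (b - 1L)) * (b > 0L), nbins = ng * ng), ng, ng)
}

#' Gray-level run-length matrix
#'
#' Decomposes the masked voxels into maximal constant-level runs along
#' each direction.  Voxels outside the mask break runs.  For each
#' direction, voxel-count conservation holds:
#' `sum over (i, l) of l * r(i, l)` equals the number of masked voxels.
#'
#' @inheritParams glcm
#' @return an object of class `glrlm_matrix`: `counts` (the aggregate,
#'   summed over directions), `per_direction`, `n_levels`, `n_voxels`.
#' @export
glrlm <- function(disc, directions = texture_directions(), geom = NULL) {
  stopifnot(inherits(disc, "discretized_volume"))
  ng <- disc$n_levels
  lv <- disc$levels
  dims <- dim(lv)
  if (is.null(geom)) geom <- glrlm_geometry(!is.na(lv), directions)
  level <- lv[geom$mask_idx]
  n_vox <- length(level)
  max_len <- max(dims)
  per <- vector("list", nrow(directions))
  for (r in seq_len(nrow(directions))) {
    ord <- geom$ord[[r]]
    le <- level[ord]
    new_run <- c(TRUE, !geom$same_line[[r]] | le[-1] != le[-n_vox])
    starts <- which(new_run)
    run_len <- diff(c(starts, n_vox + 1L))
    run_lvl <- le[starts]
    per[[r]] <- matrix(
      tabulate(run_lvl + ng * (run_len - 1L), nbins = ng * max_len),
      ng, max_len)
  }
  counts <- Reduce(`+`, per)
  structure(list(counts = counts, per_direction = per, n_levels = ng,
                 n_voxels = n_vox, directions = directions),
            class = "glrlm_matrix")
}

# Mask-only part of the run decomposition: for each direction, the order
# that sorts masked voxels along their lines and, for consecutive sorted
# pairs, whether they continue the same line with adjacent steps.  The
# geometry depends only on the mask, so it can be shared across image
# channels.
glrlm_geometry <- function(mask, directions = texture_directions()) {
  idx <- which(mask, arr.ind = TRUE)
  n_vox <- nrow(idx)
  dims <- dim(mask)
  ords <- vector("list", nrow(directions))
  same <- vector("list", nrow(directions))
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    ax <- which(d != 0)[1]
    s <- idx[, ax] * sign(d[ax])              # step index along the line
    base <- idx - outer(s, d)                 # line anchor point
    off <- 2L * max(dims) + 3L
    w <- 4L * max(dims) + 7L
    lineid <- (base[, 1] + off) + (base[, 2] + off) * w +
      (base[, 3] + off) * w * w
    ord <- order(lineid, s, method = "radix")
    li <- lineid[ord]; si <- s[ord]
    ords[[r]] <- ord
    same[[r]] <- if (n_vox > 1)
      li[-1] == li[-n_vox] & si[-1] == si[-n_vox] + 1L else logical(0)
  }
  list(mask_idx = which(mask), ord = ords, same_line = same,
       n_voxels = n_vox)
}

#' Gray-level dependence matrix
#'
#' For every masked voxel, counts its "dependent" neighbours: masked
#' voxels within Chebyshev distance `delta` whose gray level differs from
#' the centre level by at most `alpha`.  Entry `d(i, j)` is the number of
#' masked voxels with level `i` and exactly `j` dependent neighbours
#' (column index `j + 1`, since `j` starts at 0).  The entries sum to the
#' number of masked voxels.
#'
#' @inheritParams glcm
#' @param alpha gray-level similarity cutoff (>= 0).
#' @param delta Chebyshev neighbourhood radius in voxels (>= 1).
#' @return an object of class `gldm_matrix`: `counts`, `n_levels`,
#'   `n_voxels`, `alpha`, `delta`.
#' @export
gldm <- function(disc, alpha = 0, delta = 1L) {
  stopifnot(inherits(disc, "discretized_volume"), alpha >= 0, delta >= 1)
  ng <- disc$n_levels
  dims <- dim(disc$levels)
  delta <- as.integer(delta)
  # embed in a sentinel border of width delta; neighbour lookups become
  # fixed linear offsets on the flattened array, and out-of-bounds
  # neighbours land on sentinel cells that never match a real level
  pd <- dims + 2L * delta
  lvp <- array(-1048576L, pd)
  lvp[delta + (1:dims[1]), delta + (1:dims[2]), delta + (1:dims[3])] <-
    sentinel_levels(disc)
  lvp <- as.integer(lvp)
  n <- length(lvp)
  dep <- integer(n)
  rng <- -delta:delta
  for (dx in rng) for (dy in rng) for (dz in rng) {
    d <- c(dx, dy, dz)
    nz <- d[d != 0]
    if (!length(nz) || nz[1] < 0) next  # one representative per +/- pair
    s <- abs(dx + pd[1] * (dy + pd[2] * dz))
    lo <- seq_len(n - s)
    hi <- lo + s
    m <- abs(lvp[lo] - lvp[hi]) <= alpha
    # symmetric relation: credit the dependence to both pair members
    dep[lo] <- dep[lo] + m
    dep[hi] <- dep[hi] + m
  }
  keep <- lvp > 0L
  centre_lvl <- lvp[keep]
  centre_dep <- dep[keep]
  max_dep <- max(centre_dep)
  counts <- matrix(
    tabulate(centre_lvl + ng * centre_dep, nbins = ng * (max_dep + 1L)),
    ng, max_dep + 1L)
  structure(list(counts = counts, n_levels = ng, n_voxels = sum(keep),
                 alpha = alpha, delta = delta),
            class = "gldm_matrix")
}
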