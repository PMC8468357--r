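#' Flood-fill parameters
#'
#' Controls for seeded region growing: the intensity tolerance around the
#' reference value, the voxel connectivity, the neighbourhood radius used
#' for leak prevention, a safety cap on region size, and how the reference
#' intensity is defined.
#'
#' With `neighborhood_size > 0`, a candidate voxel must pass the tolerance
#' test both with its own intensity and with the mean intensity of the
#' cubic neighbourhood of that radius around it.  Thin, one-voxel bridges
#' between structures fail the neighbourhood test, which blocks leakage
#' into adjacent tissue.
#'
#' @param tolerance maximum accepted `|I(v) - reference|`, intensity units.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full cube).
#' @param neighborhood_size cubic neighbourhood radius in voxels (0 = off).
#' @param max_voxels safety cap on region size.
#' @param reference_mode `"seed-mean"` (mean intensity of the seed voxels,
#'   robust to a noisy single seed) or `"seed-intensity"` (first seed only).
#' @return an object of class `flood_fill_params`.
#' @export
flood_fill_params <- function(tolerance, connectivity = 6L,
                              neighborhood_size = 0L, max_voxels = Inf,
                              reference_mode = c("seed-mean",
                                                 "seed-intensity")) {
  if (!is.numeric(tolerance) || tolerance < 0)
    stop("tolerance must be >= 0", call. = FALSE)
  if (neighborhood_size < 0)
    stop("neighborhood_size must be >= 0", call. = FALSE)
  if (max_voxels < 1)
    stop("max_voxels must be >= 1", call. = FALSE)
  connectivity_offsets(connectivity)  # validates
  structure(
    list(tolerance = as.numeric(tolerance),
         connectivity = as.integer(connectivity),
         neighborhood_size = as.integer(neighborhood_size),
         max_voxels = max_voxels,
         reference_mode = match.arg(reference_mode)),
    class = "flood_fill_params")
}

#' Seeded flood-fill segmentation
#'
#' Grows a region from seed voxels across a 3D volume.  A candidate voxel
#' is accepted iff it is connected (under `params$connectivity`) to an
#' already accepted voxel, its intensity lies within `params$tolerance` of
#' the reference intensity, and — when `params$neighborhood_size > 0` — the
#' mean intensity of its cubic neighbourhood also lies within tolerance.
#' Acceptance is a property of the voxel alone, so the result is the
#' connected component of the acceptable voxel set containing the seeds and
#' does not depend on traversal order.  Seeds are always included.
#'
#' @param volume a [volume3d()].
#' @param seeds integer matrix with one `(x, y, z)` voxel index per row
#'   (1-based), or a length-3 vector for a single seed.
#' @param params a [flood_fill_params()].
#' @return a [segmentation_mask()] with `method = "semiauto"` provenance
#'   unset (tag it downstream).
#' @export
flood_fill <- function(volume, seeds, params) {
  stopifnot(inherits(volume, "volume3d"), inherits(params, "flood_fill_params"))
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (!nrow(seeds)) stop("at least one seed is required", call. = FALSE)
  dims <- dim(volume$intensities)
  inb <- seeds[, 1] >= 1 & seeds[, 1] <= dims[1] &
    seeds[, 2] >= 1 & seeds[, 2] <= dims[2] &
    seeds[, 3] >= 1 & seeds[, 3] <= dims[3]
  if (!all(inb))
    stop("invalid seed: seed voxel outside volume bounds (row ",
         which(!inb)[1], ")", call. = FALSE)
  v <- volume$intensities
  lin <- seeds[, 1] + dims[1] * ((seeds[, 2] - 1L) + dims[2] * (seeds[, 3] - 1L))
  reference <- switch(params$reference_mode,
    "seed-mean" = mean(v[lin]),
    "seed-intensity" = v[lin[1]])
  acceptable <- abs(v - reference) <= params$tolerance
  if (params$neighborhood_size > 0L) {
    nb <- box_mean(v, params$neighborhood_size)
    acceptable <- acceptable & (abs(nb - reference) <= params$tolerance)
  }
  acceptable[lin] <- TRUE  # seeds are always part of the region
  grown <- grow_region(acceptable, lin, params$connectivity,
                       max_voxels = params$max_voxels)
  segmentation_mask(grown, spacing = volume$spacing, method = "semiauto")
}

#' Deterministic mask cleanup
#'
#' Replaces the interactive post-editing step of a segmentation session
#' with a reproducible rule: keep the largest face-connected component and
#' fill any fully enclosed holes (background regions with no path to the
#' volume border).  Idempotent.
#'
#' @param mask a nonempty [segmentation_mask()].
#' @return the cleaned [segmentation_mask()] (provenance preserved).
#' @export
finalize_mask <- function(mask) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (!any(mask$data)) stop("empty mask", call. = FALSE)
  dims <- dim(mask$data)
  # work on a padded bounding box so border bookkeeping stays local
  bb <- mask_bbox(mask$data, pad = 1L)
  sub <- crop_bbox(mask$data, bb)
  comps <- connected_components(sub, connectivity = 6L)
  keep <- array(FALSE, dim(sub))
  keep[comps[[1]]] <- TRUE
  # background reachable from the crop border; 6-connectivity on the
  # complement is the dual of 26-connectivity holes, a standard pairing
  bg <- !keep
  border <- which(is_border_voxel(dim(sub)) & bg)
  if (length(border)) {
    outside <- grow_region(bg, border, connectivity = 6L)
    keep[!keep & !outside] <- TRUE  # enclosed holes
  } else {
    keep[] <- TRUE
  }
  out <- array(FALSE, dims)
  out[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- keep
  res <- mask
  res$data <- out
  res
}

is_border_voxel <- function(dims) {
  b <- array(FALSE, dims)
  b[c(1, dims[1]), , ] <- TRUE
  b[, c(1, dims[2]), ] <- TRUE
  b[, , c(1, dims[3])] <- TRUE
  b
}
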