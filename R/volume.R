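#' 3D image volumes and segmentation masks
#'
#' `volume3d()` wraps a 3D numeric array of voxel intensities together with
#' its physical voxel spacing (mm per axis) and origin.  Arrays are indexed
#' `[x, y, z]`, 1-based in R; voxel `(i, j, k)` has physical centre
#' `origin + (i - 1, j - 1, k - 1) * spacing`.
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric length-3, mm per axis; all components > 0.
#' @param origin numeric length-3, mm; defaults to the zero vector.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  structure(
    list(intensities = intensities, spacing = spacing,
         origin = as.numeric(origin)),
    class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$intensities)

#' Construct a segmentation mask
#'
#' A binary voxel mask aligned to a [volume3d()] (same dimensions and
#' spacing), carrying provenance: which subject it delineates, by which
#' method (`"manual"`, `"semiauto"` or `"truth"`), which observer and which
#' session.
#'
#' @param data logical (or 0/1) 3D array.
#' @param spacing voxel spacing in mm, as in [volume3d()].
#' @param subject,method,observer,session provenance tags.
#' @return an object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(data, spacing = c(1, 1, 1),
                              subject = NA_integer_,
                              method = c("truth", "manual", "semiauto"),
                              observer = NA_integer_,
                              session = NA_integer_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array", call. = FALSE)
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be binary (0/1)", call. = FALSE)
    data <- array(data > 0, dim(data))
  }
  method <- match.arg(method)
  structure(
    list(data = data, spacing = as.numeric(spacing),
         provenance = list(subject = subject, method = method,
                           observer = observer, session = session)),
    class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$data)
  p <- x$provenance
  cat(sprintf(
    "<segmentation_mask> %d x %d x %d, %d voxels set [subject %s, %s, obs %s, sess %s]\n",
    d[1], d[2], d[3], sum(x$data), p$subject, p$method, p$observer, p$session))
  invisible(x)
}

#' @export
dim.segmentation_mask <- function(x) dim(x$data)

#' Mask voxel count and physical volume
#'
#' @param mask a [segmentation_mask()].
#' @return `mask_volume()` returns the physical volume in mm^3;
#'   `mask_count()` the number of set voxels.
#' @export
mask_volume <- function(mask) sum(mask$data) * prod(mask$spacing)

#' @rdname mask_volume
#' @export
mask_count <- function(mask) sum(mask$data)

#' Dice overlap between two masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b [segmentation_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)))
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(a$data & b$data) / (sa + sb)
}

check_alignment <- function(volume, mask, vol_name = "volume",
                            mask_name = "mask") {
  if (!identical(dim(volume$intensities), dim(mask$data)) ||
      max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop("alignment error: ", mask_name, " does not match the grid of ",
         vol_name, " (dims ", paste(dim(mask$data), collapse = "x"), " vs ",
         paste(dim(volume$intensities), collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

#' Read and write volumes and masks as NIfTI
#'
#' Lossless round-trip of the intensity grid and voxel spacing through
#' NIfTI-1 files (`.nii` or `.nii.gz`).  Mask provenance is not stored in
#' the NIfTI header; the study manifest carries it.
#'
#' @param path file path.
#' @param volume a [volume3d()].
#' @param mask a [segmentation_mask()].
#' @param ... provenance fields passed to [segmentation_mask()] when reading.
#' @return readers return the reconstructed object; writers return the path
#'   invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$intensities)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, ...) {
  img <- RNifti::readNifti(path)
  segmentation_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
                    spacing = RNifti::pixdim(img)[1:3], ...)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
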