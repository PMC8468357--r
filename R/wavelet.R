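# Single-level undecimated (stationary) 3D wavelet decomposition.

# Coiflet-1 analysis filter bank (6 taps).  The low-pass taps sum to
# sqrt(2) and the high-pass taps to 0, so a constant image has an exactly
# zero response in every channel with at least one high-pass axis.
coif1_filters <- function() {
  lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
          0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
  hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
          0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  list(lo = lo, hi = hi)
}

# Circular convolution of a 3D array along one axis:
# out[i] = sum_k h[k] * a[wrap(i + k - ceil(L/2))].
# Arrays shorter than the filter support are symmetrically extended first
# (with a warning) so the periodic index arithmetic stays meaningful.
conv_axis <- function(a, h, axis) {
  n <- dim(a)[axis]
  L <- length(h)
  extended <- FALSE
  if (n < L) {
    warning("axis ", axis, " shorter than the wavelet filter support (", n,
            " < ", L, "); applying symmetric padding", call. = FALSE)
    reps <- ceiling(L / n) + 1L
    idx_ext <- integer(0)
    fwd <- seq_len(n)
    for (r in seq_len(reps)) {
      idx_ext <- c(idx_ext, if (r %% 2L == 1L) fwd else rev(fwd))
    }
    a <- index_axis(a, idx_ext, axis)
    extended <- TRUE
    n_full <- length(idx_ext)
  } else {
    n_full <- n
  }
  centre <- ceiling(L / 2)
  out <- array(0, dim(a))
  for (k in seq_len(L)) {
    idx <- ((seq_len(n_full) + k - centre - 1L) %% n_full) + 1L
    out <- out + h[k] * index_axis(a, idx, axis)
  }
  if (extended) out <- index_axis(out, seq_len(n), axis)
  out
}

index_axis <- function(a, idx, axis) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Undecimated wavelet decomposition of a volume
#'
#' Applies a single-level stationary (undecimated) 3D wavelet transform:
#' the Coiflet-1 low- (`L`) or high-pass (`H`) analysis filter is applied
#' by circular convolution along each axis, giving the eight channels
#' `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH`.  Channel labels give the
#' filter per axis in `X, Y, Z` order (first letter = X axis).  No
#' downsampling takes place, so every channel keeps the input grid and
#' the original mask applies unchanged.
#'
#' @param x 3D numeric array (typically a bounding-box crop around the
#'   region of interest).
#' @return named list of eight 3D arrays with the input dimensions.
#' @export
wavelet_decompose <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  f <- coif1_filters()
  bank <- list(L = f$lo, H = f$hi)
  out <- list()
  step_x <- list(L = conv_axis(x, f$lo, 1L), H = conv_axis(x, f$hi, 1L))
  for (fx in c("L", "H")) {
    step_y <- list(L = conv_axis(step_x[[fx]], f$lo, 2L),
                   H = conv_axis(step_x[[fx]], f$hi, 2L))
    for (fy in c("L", "H")) {
      for (fz in c("L", "H")) {
        lab <- paste0(fx, fy, fz)
        out[[lab]] <- conv_axis(step_y[[fy]], bank[[fz]], 3L)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}
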