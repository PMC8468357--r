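# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed
#'
#' Mixes a base seed with one or more integer tags (subject index, observer
#' index, session index, ...) into a new seed below 2^31, so that every
#' stochastic sub-task of a study has its own reproducible RNG stream.
#'
#' @param seed base integer seed.
#' @param ... integer tags identifying the sub-task.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    # Lehmer-style mixing; doubles stay well below 2^53 so arithmetic is exact
    h <- (h * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Connectivity offset tables: rows are (dx, dy, dz) voxel offsets.
connectivity_offsets <- function(connectivity = c(6L, 18L, 26L)) {
  connectivity <- as.integer(connectivity[1])
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = ord == 1,
    "18" = ord >= 1 & ord <= 2,
    "26" = ord >= 1)
  unname(g[keep, , drop = FALSE])
}

# Grow a region from seed linear indices over an `acceptable` logical array,
# using the given connectivity.  Pure frontier dilation; order-invariant by
# construction (the result is the connected component of `acceptable`
# containing the seeds).  Returns a logical array.
grow_region <- function(acceptable, seeds_idx, connectivity = 6L,
                        max_voxels = Inf) {
  dims <- dim(acceptable)
  offs <- connectivity_offsets(connectivity)
  visited <- array(FALSE, dims)
  visited[seeds_idx] <- TRUE
  frontier <- unique(as.integer(seeds_idx))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  while (length(frontier)) {
    if (sum(visited) > max_voxels)
      stop("flood fill exceeded max_voxels cap (", max_voxels, ")",
           call. = FALSE)
    f0 <- frontier - 1L
    x <- f0 %% nx
    y <- (f0 %/% nx) %% ny
    z <- f0 %/% (nx * ny)
    nxt <- integer(0)
    for (r in seq_len(nrow(offs))) {
      xx <- x + offs[r, 1]; yy <- y + offs[r, 2]; zz <- z + offs[r, 3]
      ok <- xx >= 0L & xx < nx & yy >= 0L & yy < ny & zz >= 0L & zz < nz
      if (!any(ok)) next
      lin <- xx[ok] + nx * (yy[ok] + ny * zz[ok]) + 1L
      lin <- lin[acceptable[lin] & !visited[lin]]
      if (length(lin)) {
        visited[lin] <- TRUE
        nxt <- c(nxt, lin)
      }
    }
    frontier <- unique(nxt)
  }
  visited
}

# Label all connected components of a logical array; returns a list of
# integer index vectors, one per component, largest first.
connected_components <- function(mask, connectivity = 6L) {
  remaining <- mask
  comps <- list()
  repeat {
    idx <- which(remaining)
    if (!length(idx)) break
    comp <- grow_region(remaining, idx[1], connectivity)
    comps[[length(comps) + 1L]] <- which(comp)
    remaining[comp] <- FALSE
  }
  if (length(comps) > 1L)
    comps <- comps[order(lengths(comps), decreasing = TRUE)]
  comps
}

# Mean over a cubic neighbourhood of half-width `r` (in-bounds voxels only),
# computed with a 3D summed-area table.
box_mean <- function(a, r) {
  r <- as.integer(r)
  if (r <= 0L) return(a)
  dims <- dim(a)
  # summed-area table with a zero layer in front of each axis
  s <- array(0, dims + 1L)
  s[-1, -1, -1] <- a
  s <- apply(s, c(2, 3), cumsum)                      # cumsum along axis 1
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))   # along axis 2
  s <- aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))   # along axis 3
  x1 <- pmax(seq_len(dims[1]) - r, 1L); x2 <- pmin(seq_len(dims[1]) + r, dims[1])
  y1 <- pmax(seq_len(dims[2]) - r, 1L); y2 <- pmin(seq_len(dims[2]) + r, dims[2])
  z1 <- pmax(seq_len(dims[3]) - r, 1L); z2 <- pmin(seq_len(dims[3]) + r, dims[3])
  # box bounds are separable per axis, so vector-indexed corner sums broadcast
  take <- function(xi, yi, zi) s[xi + 1L, yi + 1L, zi + 1L, drop = FALSE]
  tot <- take(x2, y2, z2) - take(x1 - 1L, y2, z2) - take(x2, y1 - 1L, z2) -
    take(x2, y2, z1 - 1L) + take(x1 - 1L, y1 - 1L, z2) +
    take(x1 - 1L, y2, z1 - 1L) + take(x2, y1 - 1L, z1 - 1L) -
    take(x1 - 1L, y1 - 1L, z1 - 1L)
  cnt <- outer(outer(x2 - x1 + 1, y2 - y1 + 1), z2 - z1 + 1)
  array(tot, dims) / cnt
}

# Bounding box of a logical array, optionally padded and clamped to bounds.
mask_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("mask is empty", call. = FALSE)
  dims <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, dims)
  list(lo = lo, hi = hi)
}

crop_bbox <- function(a, bb) {
  a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3], drop = FALSE]
}

fmt_num <- function(x) sprintf("%.17g", x)
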