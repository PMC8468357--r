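# Mesh-based and moment-based 3D shape descriptors of a binary mask.

# Body-centred decomposition of the unit cube into 24 tetrahedra: sample
# points are the 8 corners (ids 1-8), the 6 face centres (9-14) and the
# cube centre (15); each tetrahedron joins the centre, one face centre and
# one edge of that face.  Face-centre and centre values are averages of
# their corners, which makes the triangulation far less direction-biased
# than a plain 6-tetrahedra split.
.cube_samples <- local({
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  faces <- rbind(c(0, 0.5, 0.5), c(1, 0.5, 0.5),
                 c(0.5, 0, 0.5), c(0.5, 1, 0.5),
                 c(0.5, 0.5, 0), c(0.5, 0.5, 1))
  unname(rbind(corners, faces, c(0.5, 0.5, 0.5)))
})
.cube_tets <- local({
  corners <- .cube_samples[1:8, ]
  tets <- list()
  for (fid in 1:6) {
    fc <- .cube_samples[8L + fid, ]
    ax <- which(fc %in% c(0, 1))
    on_face <- which(corners[, ax] == fc[ax])
    # the 4 edges of this face, as corner-id pairs differing in one axis
    for (i in seq_along(on_face)) for (j in seq_along(on_face)) {
      if (i < j && sum(corners[on_face[i], ] != corners[on_face[j], ]) == 1)
        tets[[length(tets) + 1L]] <-
          c(15L, 8L + fid, on_face[i], on_face[j])
    }
  }
  do.call(rbind, tets)
})

# Triangulated isosurface of a binary mask at the half level, by marching
# tetrahedra on the voxel-centre lattice with linear interpolation of the
# crossing point along each lattice edge.  The binary indicator is first
# anti-aliased with a small Gaussian (sigma in voxels) so that the surface
# estimate of smooth objects is approximately unbiased — a raw staircase
# mesh overestimates the area of oblique and curved surfaces — while flat
# axis-aligned faces stay in place (the smoothed field keeps its 0.5 level
# on the face plane).  The mask is padded with background so the surface
# always closes; the enclosed volume comes from the divergence theorem
# over the consistently oriented triangles, which is exact for the mesh.
mask_mesh <- function(maskdata, spacing, sigma = 0.6) {
  dims <- dim(maskdata)
  pad <- max(2L, ceiling(3 * sigma) + 1L)
  f <- array(0, dims + 2L * pad)
  f[pad + (1:dims[1]), pad + (1:dims[2]), pad + (1:dims[3])] <-
    as.numeric(maskdata)
  if (sigma > 0) {
    rad <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(-rad:rad, sd = sigma)
    kern <- kern / sum(kern)
    # zero-padded (not periodic) smoothing: the pad layer stays background
    for (ax in 1:3) f <- conv_axis_zeropad(f, kern, ax)
  }
  pd <- dim(f)
  cx <- pd[1] - 1L; cy <- pd[2] - 1L; cz <- pd[3] - 1L
  corner <- vector("list", 15L)
  for (cid in 1:8) {
    o <- .cube_samples[cid, ]
    corner[[cid]] <- as.vector(f[(1:cx) + o[1], (1:cy) + o[2], (1:cz) + o[3]])
  }
  # face-centre (9-14) and body-centre (15) samples: corner averages
  for (sid in 9:15) {
    o <- .cube_samples[sid, ]
    touching <- which(vapply(1:8, function(cid)
      all(abs(.cube_samples[cid, ] - o) <= 0.5), logical(1)))
    corner[[sid]] <- Reduce(`+`, corner[touching]) / length(touching)
  }
  # samples sitting exactly at the iso-level are nudged inside, the
  # standard tie-break that keeps the triangulated surface watertight
  corner <- lapply(corner, function(x) {
    x[abs(x - 0.5) < 1e-9] <- 0.5 + 1e-7
    x
  })
  # only cells whose corners straddle the iso-level can carry surface;
  # interior cells contribute no triangles (and the divergence-theorem
  # volume needs the surface only), so restrict all tetrahedra work to
  # the boundary shell
  ins8 <- lapply(corner[1:8], function(x) x > 0.5)
  n_in <- Reduce(`+`, ins8)
  active <- which(n_in > 0L & n_in < 8L)
  corner <- lapply(corner, function(x) x[active])
  inside_c <- lapply(corner, function(x) x > 0.5)
  volume <- 0
  area <- 0
  a0 <- active - 1L
  # physical coordinates of every sample point, componentwise, per cell
  base_x <- (a0 %% cx - pad) * spacing[1]
  base_y <- ((a0 %/% cx) %% cy - pad) * spacing[2]
  base_z <- (a0 %/% (cx * cy) - pad) * spacing[3]
  samp_x <- lapply(1:15, function(i) base_x + .cube_samples[i, 1] * spacing[1])
  samp_y <- lapply(1:15, function(i) base_y + .cube_samples[i, 2] * spacing[2])
  samp_z <- lapply(1:15, function(i) base_z + .cube_samples[i, 3] * spacing[3])
  for (t in seq_len(nrow(.cube_tets))) {
    ids <- .cube_tets[t, ]
    b <- inside_c[[ids[1]]] + 2L * inside_c[[ids[2]]] +
      4L * inside_c[[ids[3]]] + 8L * inside_c[[ids[4]]]
    mixed <- which(b > 0L & b < 15L)
    if (!length(mixed)) next
    bm <- b[mixed]
    for (s in sort(unique(bm))) {
      cells <- mixed[bm == s]
      inside <- which(bitwAnd(s, c(1L, 2L, 4L, 8L)) > 0L)
      # interpolated crossing point on the edge between local corners u, v
      cross_pt <- function(u, v) {
        iu <- ids[u]; iv <- ids[v]
        fu <- corner[[iu]][cells]
        tt <- (0.5 - fu) / (corner[[iv]][cells] - fu)
        list(x = samp_x[[iu]][cells] + tt * (samp_x[[iv]][cells] - samp_x[[iu]][cells]),
             y = samp_y[[iu]][cells] + tt * (samp_y[[iv]][cells] - samp_y[[iu]][cells]),
             z = samp_z[[iu]][cells] + tt * (samp_z[[iv]][cells] - samp_z[[iu]][cells]))
      }
      ir <- ids[inside[1]]
      for (tr in .tet_tris[[s]]) {
        v1 <- cross_pt(tr[[1]][1], tr[[1]][2])
        v2 <- cross_pt(tr[[2]][1], tr[[2]][2])
        v3 <- cross_pt(tr[[3]][1], tr[[3]][2])
        ux <- v2$x - v1$x; uy <- v2$y - v1$y; uz <- v2$z - v1$z
        wx <- v3$x - v1$x; wy <- v3$y - v1$y; wz <- v3$z - v1$z
        nx_ <- uy * wz - uz * wy
        ny_ <- uz * wx - ux * wz
        nz_ <- ux * wy - uy * wx
        area <- area + 0.5 * sum(sqrt(nx_^2 + ny_^2 + nz_^2))
        # signed tetra volume about the origin; flip the sign where the
        # triangle normal points toward the inside reference corner
        det <- v1$x * (v2$y * v3$z - v2$z * v3$y) -
               v1$y * (v2$x * v3$z - v2$z * v3$x) +
               v1$z * (v2$x * v3$y - v2$y * v3$x)
        inward <- nx_ * (samp_x[[ir]][cells] - v1$x) +
                  ny_ * (samp_y[[ir]][cells] - v1$y) +
                  nz_ * (samp_z[[ir]][cells] - v1$z) > 0
        volume <- volume + sum(det * (1 - 2 * inward)) / 6
      }
    }
  }
  list(volume = abs(volume), area = area)
}

conv_axis_zeropad <- function(a, kern, axis) {
  n <- dim(a)[axis]
  rad <- (length(kern) - 1L) / 2L
  out <- array(0, dim(a))
  for (k in seq_along(kern)) {
    off <- k - rad - 1L
    idx <- seq_len(n) + off
    src <- idx >= 1L & idx <= n
    dst <- which(src)
    out_slice <- index_axis_assign(out, dst, kern[k], a, idx[src], axis)
    out <- out_slice
  }
  out
}

index_axis_assign <- function(out, dst, w, a, src, axis) {
  switch(axis,
         { out[dst, , ] <- out[dst, , ] + w * a[src, , , drop = FALSE]; out },
         { out[, dst, ] <- out[, dst, ] + w * a[, src, , drop = FALSE]; out },
         { out[, , dst] <- out[, , dst] + w * a[, , src, drop = FALSE]; out })
}

# Triangles cut by the half-level surface inside one tetrahedron, expressed
# as lists of local-corner pairs (each vertex is the crossing point on an
# edge between an inside and an outside corner); tabulated per case value
# in .tet_tris below.
tet_case_triangles <- function(inside) {
  outside <- setdiff(1:4, inside)
  if (length(inside) == 1L) {
    a <- inside
    list(list(c(a, outside[1]), c(a, outside[2]), c(a, outside[3])))
  } else if (length(inside) == 3L) {
    b <- outside
    list(list(c(inside[1], b), c(inside[2], b), c(inside[3], b)))
  } else {
    a <- inside[1]; b <- inside[2]; c_ <- outside[1]; d <- outside[2]
    list(list(c(a, c_), c(a, d), c(b, d)),
         list(c(a, c_), c(b, d), c(b, c_)))
  }
}

.tet_tris <- local({
  lapply(1:14, function(s) {
    tet_case_triangles(which(bitwAnd(s, c(1L, 2L, 4L, 8L)) > 0L))
  })
})

# Largest pairwise Euclidean distance among the corner points of the
# masked boundary voxels.  The diameter is attained on the convex hull;
# corner points share a discrete set of exact z-levels, and every 3D hull
# vertex is extreme within its z-level's 2D section, so candidates are
# pruned to the per-level 2D hulls before the quadratic sweep.
mask_corner_diameter <- function(sub, spacing) {
  dims <- dim(sub)
  inner <- array(TRUE, dims)
  for (ax in 1:3) {
    n <- dims[ax]
    if (n < 2) { inner[] <- FALSE; break }
    lo <- index_axis(sub, c(1L, seq_len(n - 1L)), ax)
    hi <- index_axis(sub, c(seq_len(n - 1L) + 1L, n), ax)
    inner <- inner & lo & hi
  }
  # border voxels of the crop are boundary by construction (pad = 1)
  bidx <- which(sub & !inner, arr.ind = TRUE)
  if (!nrow(bidx)) bidx <- which(sub, arr.ind = TRUE)
  # corner offsets in half-voxel units; dedupe on the half-integer lattice
  pts <- NULL
  for (ox in c(-1L, 1L)) for (oy in c(-1L, 1L)) for (oz in c(-1L, 1L)) {
    pts <- rbind(pts, cbind(2L * bidx[, 1] + ox, 2L * bidx[, 2] + oy,
                            2L * bidx[, 3] + oz))
  }
  key <- pts[, 1] + 2 * (dims[1] + 2) *
    (pts[, 2] + 2 * (dims[2] + 2) * pts[, 3])
  pts <- pts[!duplicated(key), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(pts)), pts[, 3]), function(ii) {
    if (length(ii) <= 3L) return(ii)
    ii[grDevices::chull(pts[ii, 1], pts[ii, 2])]
  }), use.names = FALSE)
  p <- sweep(pts[keep, , drop = FALSE] / 2, 2, spacing, "*")
  sq <- rowSums(p^2)
  best <- 0
  chunk <- 2048L
  for (start in seq(1L, nrow(p), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(p))
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(p[idx, , drop = FALSE], p)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' 3D shape features of a segmentation mask
#'
#' Computes the 14 shape descriptors: Voxel Volume, Maximum 3D Diameter,
#' Mesh Volume, Major Axis Length, Sphericity, Least Axis Length,
#' Elongation, Surface Volume Ratio, Maximum 2D Diameter (Slice),
#' Flatness, Surface Area, Minor Axis Length, Maximum 2D Diameter
#' (Column), Maximum 2D Diameter (Row).
#'
#' Mesh Volume and Surface Area come from a half-level triangulated
#' isosurface of the mask (marching tetrahedra on the voxel-centre
#' lattice); Sphericity is `(36 pi V^2)^(1/3) / A`.  The maximum 3D
#' diameter is the largest distance between surface-mesh vertices.  The
#' 2D diameters take, per slice of the respective orientation (Slice =
#' axial x-y, Column = coronal x-z, Row = sagittal y-z), the largest
#' in-plane distance between corners of masked voxels, maximized over
#' slices.  Axis lengths are `4 * sqrt(lambda)` for the ordered
#' eigenvalues of the physical-coordinate covariance (population
#' normalization) of the masked voxel centres; Elongation and Flatness
#' are `sqrt(lambda_minor / lambda_major)` and
#' `sqrt(lambda_least / lambda_major)`.
#'
#' Shape features are computed on the original (non-filtered) geometry
#' only, independent of gray levels.
#'
#' @param mask a [segmentation_mask()] with at least 4 voxels; run
#'   [finalize_mask()] upstream if the mask may have several components.
#' @param spacing optional spacing override (mm per axis).
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "segmentation_mask"))
  spacing <- spacing %||% mask$spacing
  md <- mask$data
  nvox <- sum(md)
  if (nvox < 4)
    stop("degenerate shape: mask has fewer than 4 voxels ",
         "(coordinate covariance would be rank-deficient)", call. = FALSE)
  bb <- mask_bbox(md, pad = 1L)
  sub <- crop_bbox(md, bb)
  mesh <- mask_mesh(sub, spacing)
  v_mesh <- mesh$volume
  a_mesh <- mesh$area
  idx <- which(sub, arr.ind = TRUE)
  pts <- sweep(idx, 2, spacing, "*")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  lambda <- sort(eigen(crossprod(cc) / nvox, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  lambda <- pmax(lambda, 0)
  c(
    VoxelVolume = nvox * prod(spacing),
    Maximum3DDiameter = mask_corner_diameter(sub, spacing),
    MeshVolume = v_mesh,
    MajorAxisLength = 4 * sqrt(lambda[1]),
    Sphericity = (36 * pi * v_mesh^2)^(1 / 3) / a_mesh,
    LeastAxisLength = 4 * sqrt(lambda[3]),
    Elongation = if (lambda[1] > 0) sqrt(lambda[2] / lambda[1]) else 0,
    SurfaceVolumeRatio = a_mesh / v_mesh,
    Maximum2DDiameterSlice = max_planar_diameter(idx, spacing, c(1, 2), 3),
    Flatness = if (lambda[1] > 0) sqrt(lambda[3] / lambda[1]) else 0,
    SurfaceArea = a_mesh,
    MinorAxisLength = 4 * sqrt(lambda[2]),
    Maximum2DDiameterColumn = max_planar_diameter(idx, spacing, c(1, 3), 2),
    Maximum2DDiameterRow = max_planar_diameter(idx, spacing, c(2, 3), 1)
  )
}

# Largest in-plane distance between voxel corners within any slice
# perpendicular to `fixed_axis`; the 2D convex hull keeps it exact and fast.
max_planar_diameter <- function(idx, spacing, plane_axes, fixed_axis) {
  best <- 0
  for (s in unique(idx[, fixed_axis])) {
    sl <- idx[idx[, fixed_axis] == s, plane_axes, drop = FALSE]
    u <- sl[, 1] * spacing[plane_axes[1]]
    v <- sl[, 2] * spacing[plane_axes[2]]
    hu <- spacing[plane_axes[1]] / 2
    hv <- spacing[plane_axes[2]] / 2
    pts <- cbind(c(u - hu, u - hu, u + hu, u + hu),
                 c(v - hv, v + hv, v - hv, v + hv))
    if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(pts) >= 2) {
      d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * tcrossprod(pts)
      best <- max(best, max(d2))
    }
  }
  sqrt(max(best, 0))
}
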