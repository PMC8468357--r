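# Independent brute-force oracles and fixture builders.  These deliberately
# use naive scalar algorithms (explicit stacks, triple loops, direct
# summation) so they share no code path with the package implementation.

# --- fixtures ---------------------------------------------------------------

rasterized_ball <- function(r, n = 2 * r + 5) {
  cc <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2 <= r^2, c(n, n, n))
}

solid_cube <- function(side, margin = 2) {
  n <- side + 2 * margin
  a <- array(FALSE, c(n, n, n))
  idx <- (margin + 1):(margin + side)
  a[idx, idx, idx] <- TRUE
  a
}

random_masked_volume <- function(dims, seed, n_levels = 4, p_mask = 0.7) {
  withr::with_seed(seed, {
    list(values = array(sample.int(n_levels, prod(dims), replace = TRUE),
                        dims),
         mask = array(stats::runif(prod(dims)) < p_mask, dims))
  })
}

# --- flood fill / connectivity oracle ---------------------------------------

# explicit-stack region growing, one voxel at a time
flood_oracle <- function(vol, seed_vox, tol, connectivity = 6,
                         neighborhood = 0, reference = NULL) {
  dims <- dim(vol)
  offs <- radrepro_offsets(connectivity)
  ref <- if (is.null(reference)) vol[seed_vox[1], seed_vox[2], seed_vox[3]]
         else reference
  nb_ok <- function(v) {
    if (neighborhood == 0) return(TRUE)
    xs <- max(1, v[1] - neighborhood):min(dims[1], v[1] + neighborhood)
    ys <- max(1, v[2] - neighborhood):min(dims[2], v[2] + neighborhood)
    zs <- max(1, v[3] - neighborhood):min(dims[3], v[3] + neighborhood)
    abs(mean(vol[xs, ys, zs]) - ref) <= tol
  }
  ok <- function(v) abs(vol[v[1], v[2], v[3]] - ref) <= tol && nb_ok(v)
  visited <- array(FALSE, dims)
  stack <- list(seed_vox)
  visited[seed_vox[1], seed_vox[2], seed_vox[3]] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (r in seq_len(nrow(offs))) {
      w <- v + offs[r, ]
      if (any(w < 1) || any(w > dims)) next
      if (visited[w[1], w[2], w[3]]) next
      if (ok(w)) {
        visited[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1L]] <- w
      }
    }
  }
  visited
}

radrepro_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1)
  unname(g[keep, , drop = FALSE])
}

# scalar connected-component counter for finalize_mask checks
count_components <- function(mask, connectivity = 6) {
  dims <- dim(mask)
  offs <- radrepro_offsets(connectivity)
  remaining <- mask
  n <- 0L
  while (any(remaining)) {
    stack <- list(which(remaining, arr.ind = TRUE)[1, ])
    remaining[stack[[1]][1], stack[[1]][2], stack[[1]][3]] <- FALSE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > dims)) next
        if (remaining[w[1], w[2], w[3]]) {
          remaining[w[1], w[2], w[3]] <- FALSE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    n <- n + 1L
  }
  n
}

# --- texture matrix oracles -------------------------------------------------

# ordered-pair enumeration over every voxel pair for one offset
glcm_oracle_direction <- function(levels, mask, d) {
  dims <- dim(levels)
  ng <- max(levels[mask])
  cnt <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    w <- c(x, y, z) + d
    if (any(w < 1) || any(w > dims)) next
    if (!mask[w[1], w[2], w[3]]) next
    i <- levels[x, y, z]; j <- levels[w[1], w[2], w[3]]
    cnt[i, j] <- cnt[i, j] + 1
    cnt[j, i] <- cnt[j, i] + 1
  }
  cnt
}

# walk every lattice line voxel by voxel and record maximal runs
glrlm_oracle_direction <- function(levels, mask, d) {
  dims <- dim(levels)
  ng <- max(levels[mask])
  counts <- matrix(0, ng, max(dims))
  starts <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  is_start <- function(v) {
    w <- v - d
    any(w < 1) || any(w > dims)  # no predecessor on the line
  }
  for (r in seq_len(nrow(starts))) {
    v <- as.numeric(starts[r, ])
    if (!is_start(v)) next
    run_level <- 0; run_len <- 0
    while (all(v >= 1) && all(v <= dims)) {
      lv <- if (mask[v[1], v[2], v[3]]) levels[v[1], v[2], v[3]] else 0
      if (lv == run_level && lv != 0) {
        run_len <- run_len + 1
      } else {
        if (run_level != 0)
          counts[run_level, run_len] <- counts[run_level, run_len] + 1
        run_level <- lv
        run_len <- if (lv != 0) 1 else 0
      }
      v <- v + d
    }
    if (run_level != 0)
      counts[run_level, run_len] <- counts[run_level, run_len] + 1
  }
  counts
}

# per-voxel neighbour enumeration
gldm_oracle <- function(levels, mask, alpha, delta) {
  dims <- dim(levels)
  ng <- max(levels[mask])
  recs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    dep <- 0
    for (dx in -delta:delta) for (dy in -delta:delta) for (dz in -delta:delta) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- c(x + dx, y + dy, z + dz)
      if (any(w < 1) || any(w > dims)) next
      if (!mask[w[1], w[2], w[3]]) next
      if (abs(levels[w[1], w[2], w[3]] - levels[x, y, z]) <= alpha)
        dep <- dep + 1
    }
    recs[[length(recs) + 1L]] <- c(levels[x, y, z], dep)
  }
  m <- do.call(rbind, recs)
  counts <- matrix(0, ng, max(m[, 2]) + 1)
  for (r in seq_len(nrow(m)))
    counts[m[r, 1], m[r, 2] + 1] <- counts[m[r, 1], m[r, 2] + 1] + 1
  counts
}

# --- first-order oracle -----------------------------------------------------

first_order_oracle <- function(v, p, voxel_volume = 1, eps = 2.2e-16) {
  n <- length(v)
  mu <- sum(v) / n
  ctr <- v - mu
  q <- stats::quantile(v, c(.1, .25, .5, .75, .9), names = FALSE, type = 7)
  inner <- v[v >= q[1] & v <= q[5]]
  list(Mean = mu,
       Variance = sum(ctr^2) / n,
       Skewness = if (sum(ctr^2) == 0) 0 else
         (sum(ctr^3) / n) / (sum(ctr^2) / n)^1.5,
       Kurtosis = if (sum(ctr^2) == 0) 0 else
         (sum(ctr^4) / n) / (sum(ctr^2) / n)^2,
       Energy = sum(v^2),
       TotalEnergy = voxel_volume * sum(v^2),
       RootMeanSquared = sqrt(sum(v^2) / n),
       Median = q[3], InterquartileRange = q[4] - q[2],
       Percentile10 = q[1], Percentile90 = q[5],
       Minimum = min(v), Maximum = max(v), Range = max(v) - min(v),
       MeanAbsoluteDeviation = sum(abs(ctr)) / n,
       RobustMeanAbsoluteDeviation =
         sum(abs(inner - sum(inner) / length(inner))) / length(inner),
       Entropy = -sum(p * log2(p + eps)),
       Uniformity = sum(p^2))
}

# --- wavelet oracle ---------------------------------------------------------

# naive periodic separable convolution, one output voxel at a time
wavelet_oracle_axis <- function(a, h, axis) {
  dims <- dim(a)
  out <- array(0, dims)
  L <- length(h)
  centre <- ceiling(L / 2)
  n <- dims[axis]
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    acc <- 0
    for (k in 1:L) {
      v <- c(x, y, z)
      v[axis] <- ((v[axis] + k - centre - 1) %% n) + 1
      acc <- acc + h[k] * a[v[1], v[2], v[3]]
    }
    out[x, y, z] <- acc
  }
  out
}

# --- ICC oracles ------------------------------------------------------------

# textbook mean squares through base R aov(), an independent route
anova_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   s = factor(rep(seq_len(n), k)),
                   r = factor(rep(seq_len(k), each = n)))
  two <- summary(stats::aov(y ~ s + r, df))[[1]][["Mean Sq"]]
  one <- summary(stats::aov(y ~ s, df))[[1]][["Mean Sq"]]
  list(ms_rows = two[1], ms_cols = two[2], ms_error = two[3],
       ms_within = one[2])
}

icc_a1_oracle <- function(x) {
  m <- anova_oracle(x)
  n <- nrow(x); k <- ncol(x)
  (m$ms_rows - m$ms_error) /
    (m$ms_rows + (k - 1) * m$ms_error + (k / n) * (m$ms_cols - m$ms_error))
}

icc_c1_oracle <- function(x) {
  m <- anova_oracle(x)
  k <- ncol(x)
  (m$ms_rows - m$ms_error) / (m$ms_rows + (k - 1) * m$ms_error)
}

# second, aov-free route for ICC(A,1): direct sums of squares
icc_a1_oracle2 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - g)^2)
  ss_cols <- n * sum((colMeans(x) - g)^2)
  ss_err <- sum((x - g)^2) - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# exhaustive two-sided rank-sum p-value by enumerating group assignments
wilcoxon_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  m <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)])
  combs <- utils::combn(n, m)
  ws <- apply(combs, 2, function(ii) sum(ranks[ii]))
  mu <- m * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# --- small study for pipeline-level tests -----------------------------------

tiny_design <- function(seed = 1L, ...) {
  args <- list(n_subjects = 3L, dims = c(24L, 24L, 24L),
               size_mean_low = 1.6, size_sd_low = 0.2,
               size_mean_high = 2.4, size_sd_high = 0.25,
               manual_boundary_sd = 2, rng_seed = seed)
  do.call(study_design, utils::modifyList(args, list(...)))
}

mc_design <- function(seed, ...) {
  args <- list(n_subjects = 8L, dims = c(24L, 24L, 24L),
               size_mean_low = 1.6, size_sd_low = 0.25,
               size_mean_high = 2.4, size_sd_high = 0.3,
               manual_boundary_sd = 3, semiauto_seed_jitter_sd = 1,
               rng_seed = seed)
  do.call(study_design, utils::modifyList(args, list(...)))
}

mc_features <- feature_config(channels = "original",
                              families = c("firstorder", "glcm",
                                           "glrlm", "gldm"))
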