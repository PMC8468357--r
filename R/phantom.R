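# Synthetic phantom study: MR-like volumes with ellipsoidal tumours,
# smooth observer boundary noise for the manual arm, and seeded flood-fill
# segmentation for the semi-automatic arm.

#' Study design for the synthetic reproducibility experiment
#'
#' Encodes the segmentation-study layout: a two-stage-group cohort with
#' group-specific tumour diameter distributions, several independent
#' manual delineations per subject, and repeated semi-automatic
#' segmentations by multiple observers over multiple sessions.  The
#' default design (30 subjects, 4 manual observers, 2 semi-automatic
#' observers x 2 sessions) yields 120 manual + 120 semi-automatic = 240
#' masks, with tumour diameters drawn from 3.7 +/- 0.7 cm (Stages I-II)
#' and 8.9 +/- 3.4 cm (Stages III-IV).
#'
#' @param n_subjects number of subjects.
#' @param stage_split fraction of subjects in the Stages I-II group.
#' @param manual_observers,semiauto_observers,semiauto_sessions counts.
#' @param size_mean_low,size_sd_low diameter distribution (cm), Stages I-II.
#' @param size_mean_high,size_sd_high diameter distribution (cm), Stages III-IV.
#' @param manual_boundary_sd SD of the manual observers' smooth radial
#'   boundary displacement, mm (split evenly between an observer bias
#'   field and per-session noise).
#' @param semiauto_seed_jitter_sd SD of the semi-automatic seed-placement
#'   jitter, mm.
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param contrast tumour-background intensity difference.
#' @param background_level mean background intensity.
#' @param background_texture_sd SD of the smooth background heterogeneity
#'   field (applied across the whole volume so texture matrices are
#'   non-degenerate).
#' @param texture_smoothing Gaussian smoothing sigma of the heterogeneity
#'   field, voxels.
#' @param dims volume grid size (voxels per axis).
#' @param spacing voxel spacing, mm per axis.
#' @param axis_ratio_range ellipsoid minor/major axis ratio range.
#' @param semiauto_model `"floodfill"` (default: seeds + region growing on
#'   the noisy image) or `"displacement"` (same smooth boundary-noise
#'   model as the manual arm, with `semiauto_boundary_sd`; useful for
#'   null-calibration studies where both arms must be statistically
#'   exchangeable).
#' @param semiauto_boundary_sd boundary noise SD (mm) when
#'   `semiauto_model = "displacement"`.
#' @param flood_tolerance intensity tolerance for the semi-automatic
#'   flood fill; default `contrast / 2`.
#' @param flood_neighborhood leak-prevention neighbourhood radius.
#' @param n_seeds number of seed voxels placed per flood fill.
#' @param rng_seed base seed; all randomness derives from it.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_subjects = 30L, stage_split = 0.5,
                         manual_observers = 4L, semiauto_observers = 2L,
                         semiauto_sessions = 2L,
                         size_mean_low = 3.7, size_sd_low = 0.7,
                         size_mean_high = 8.9, size_sd_high = 3.4,
                         manual_boundary_sd = 2, semiauto_seed_jitter_sd = 1,
                         noise_sd = 5, contrast = 50,
                         background_level = 100, background_texture_sd = 8,
                         texture_smoothing = 3,
                         dims = c(64L, 64L, 64L), spacing = c(1.5, 1.5, 1.5),
                         axis_ratio_range = c(0.7, 1.0),
                         semiauto_model = c("floodfill", "displacement"),
                         semiauto_boundary_sd = NULL,
                         flood_tolerance = NULL, flood_neighborhood = 0L,
                         n_seeds = 5L, rng_seed = 1L) {
  counts <- c(n_subjects, manual_observers, semiauto_observers,
              semiauto_sessions, n_seeds)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  sds <- c(size_sd_low, size_sd_high, manual_boundary_sd,
           semiauto_seed_jitter_sd, noise_sd, background_texture_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (stage_split < 0 || stage_split > 1)
    stop("stage_split must be in [0, 1]", call. = FALSE)
  semiauto_model <- match.arg(semiauto_model)
  if (semiauto_model == "displacement" && is.null(semiauto_boundary_sd))
    stop("semiauto_boundary_sd is required under the displacement model",
         call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), stage_split = stage_split,
    manual_observers = as.integer(manual_observers),
    semiauto_observers = as.integer(semiauto_observers),
    semiauto_sessions = as.integer(semiauto_sessions),
    size_mean_low = size_mean_low, size_sd_low = size_sd_low,
    size_mean_high = size_mean_high, size_sd_high = size_sd_high,
    manual_boundary_sd = manual_boundary_sd,
    semiauto_seed_jitter_sd = semiauto_seed_jitter_sd,
    noise_sd = noise_sd, contrast = contrast,
    background_level = background_level,
    background_texture_sd = background_texture_sd,
    texture_smoothing = texture_smoothing,
    dims = as.integer(dims), spacing = as.numeric(spacing),
    axis_ratio_range = axis_ratio_range,
    semiauto_model = semiauto_model,
    semiauto_boundary_sd = semiauto_boundary_sd,
    flood_tolerance = flood_tolerance,
    flood_neighborhood = as.integer(flood_neighborhood),
    n_seeds = as.integer(n_seeds), rng_seed = as.integer(rng_seed)),
    class = "study_design")
}

#' Total masks implied by a design
#'
#' `n_subjects * manual_observers` manual masks plus
#' `n_subjects * semiauto_observers * semiauto_sessions` semi-automatic
#' masks.
#'
#' @param design a [study_design()].
#' @return named integer vector with `manual`, `semiauto`, `total`.
#' @export
design_mask_counts <- function(design) {
  man <- design$n_subjects * design$manual_observers
  semi <- design$n_subjects * design$semiauto_observers *
    design$semiauto_sessions
  c(manual = man, semiauto = semi, total = man + semi)
}

#' Sample a tumour diameter for a stage group
#'
#' Gaussian draw from the group's diameter distribution, rejected and
#' redrawn while non-positive.  Truncation to the field of view happens
#' later, at rasterization, so the recorded diameters reproduce the
#' configured group statistics.
#'
#' @param stage_group `"I-II"` or `"III-IV"`.
#' @param design a [study_design()].
#' @return diameter in cm.
#' @export
sample_diameter <- function(stage_group = c("I-II", "III-IV"), design) {
  stage_group <- match.arg(stage_group)
  mu <- if (stage_group == "I-II") design$size_mean_low else design$size_mean_high
  sd_ <- if (stage_group == "I-II") design$size_sd_low else design$size_sd_high
  repeat {
    d <- stats::rnorm(1, mu, sd_)
    if (d > 0) return(d)
  }
}

# Real spherical harmonics up to degree 2, orthonormal over the sphere;
# u is an n x 3 matrix of unit direction vectors.  E[Y_i(u)^2] = 1/(4 pi)
# under uniform directions, so coefficients drawn N(0, sd^2 * 4 pi / 9)
# give a displacement field with pointwise SD ~ sd.
sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(0.28209479177387814,
        0.4886025119029199 * y,
        0.4886025119029199 * z,
        0.4886025119029199 * x,
        1.0925484305920792 * x * y,
        1.0925484305920792 * y * z,
        0.31539156525252005 * (3 * z^2 - 1),
        1.0925484305920792 * x * z,
        0.5462742152960396 * (x^2 - y^2))
}

sh_coeff_scale <- sqrt(4 * pi / 9)

# Normalized ellipsoid "radius" g(v) (<= 1 inside the tumour) over the
# whole grid, plus unit directions from the centre.
ellipsoid_field <- function(dims, spacing, center, axes, rotation) {
  coords <- cbind(
    rep_len(seq_len(dims[1]), prod(dims)) * spacing[1],
    rep_len(rep(seq_len(dims[2]), each = dims[1]), prod(dims)) * spacing[2],
    rep(seq_len(dims[3]), each = dims[1] * dims[2]) * spacing[3])
  rel <- sweep(coords, 2, center)
  local <- rel %*% rotation  # rotate into ellipsoid axes
  g <- sqrt((local[, 1] / axes[1])^2 + (local[, 2] / axes[2])^2 +
            (local[, 3] / axes[3])^2)
  r <- sqrt(rowSums(rel^2))
  r[r == 0] <- 1
  list(g = g, u = rel / r)
}

# Precomputed geometry shared by all observer simulations of a phantom:
# the normalized ellipsoid radius g(v) and the spherical-harmonic basis
# evaluated at each voxel's direction from the tumour centre.
phantom_field <- function(phantom, design) {
  ef <- ellipsoid_field(design$dims, design$spacing, phantom$center_mm,
                        phantom$axes_mm, phantom$rotation)
  list(g = ef$g, Y = sh_basis(ef$u))
}

# Gaussian-smoothed periodic white noise field, rescaled to unit SD.
smooth_field <- function(dims, sigma) {
  f <- array(stats::rnorm(prod(dims)), dims)
  if (sigma > 0) {
    rad <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(-rad:rad, sd = sigma)
    kern <- kern / sum(kern)
    for (ax in 1:3) f <- conv_axis_kernel(f, kern, ax)
  }
  (f - mean(f)) / stats::sd(f)
}

conv_axis_kernel <- function(a, kern, axis) {
  n <- dim(a)[axis]
  rad <- (length(kern) - 1L) / 2L
  out <- array(0, dim(a))
  for (k in seq_along(kern)) {
    off <- k - rad - 1L
    idx <- ((seq_len(n) + off - 1L) %% n) + 1L
    out <- out + kern[k] * index_axis(a, idx, axis)
  }
  out
}

#' Generate a phantom subject
#'
#' Builds one MR-like volume and its ground-truth tumour mask: an
#' ellipsoid (random axis ratios and orientation) whose diameter is drawn
#' from the stage group's distribution, placed on a smoothly varying
#' background with additive Gaussian noise and a fixed tumour-background
#' contrast.  Diameters exceeding the field of view are truncated at
#' rasterization with a warning.  Deterministic for a fixed seed.
#'
#' @param stage_group `"I-II"` or `"III-IV"`.
#' @param design a [study_design()].
#' @param subject_seed integer seed for this subject.
#' @param subject subject identifier carried in provenance.
#' @return an object of class `phantom`: fields `volume`, `truth_mask`,
#'   `stage_group`, `tumour_diameter` (cm, as sampled), `axes_mm`,
#'   `center_mm`, `rotation`, `subject`.
#' @export
generate_phantom <- function(stage_group = c("I-II", "III-IV"), design,
                             subject_seed, subject = NA_integer_) {
  stage_group <- match.arg(stage_group)
  stopifnot(inherits(design, "study_design"))
  dims <- design$dims
  spacing <- design$spacing
  fov <- dims * spacing
  with_seed(subject_seed, {
    d_cm <- sample_diameter(stage_group, design)
    d_mm <- d_cm * 10
    max_mm <- 0.75 * min(fov)
    min_mm <- 6 * min(spacing)
    if (d_mm > max_mm) {
      warning("sampled diameter ", round(d_cm, 2),
              " cm exceeds the field of view; truncating to ",
              round(max_mm / 10, 2), " cm", call. = FALSE)
      d_mm <- max_mm
    }
    if (d_mm < min_mm) d_mm <- min_mm
    ratios <- stats::runif(2, design$axis_ratio_range[1],
                           design$axis_ratio_range[2])
    axes <- d_mm / 2 * c(1, ratios)
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    slack <- pmax(fov / 2 - (max(axes) + 3 * spacing), 0)
    center <- fov / 2 + stats::runif(3, -1, 1) * pmin(slack, 0.1 * fov)
    ef <- ellipsoid_field(dims, spacing, center, axes, rot)
    inside <- array(ef$g <= 1, dims)
    img <- array(design$background_level, dims)
    if (design$background_texture_sd > 0)
      img <- img + design$background_texture_sd *
        smooth_field(dims, design$texture_smoothing)
    img <- img + design$contrast * inside
    if (design$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(dims), 0, design$noise_sd), dims)
    structure(list(
      volume = volume3d(img, spacing = spacing),
      truth_mask = segmentation_mask(inside, spacing = spacing,
                                     subject = subject, method = "truth"),
      stage_group = stage_group, tumour_diameter = d_cm,
      axes_mm = axes, center_mm = center, rotation = rot,
      subject = subject),
      class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> subject %s, stage %s, diameter %.2f cm, %d tumour voxels\n",
    x$subject, x$stage_group, x$tumour_diameter, sum(x$truth_mask$data)))
  invisible(x)
}

# Evaluate the deformed-ellipsoid mask for a smooth radial displacement
# field d(u) (mm): accept voxels with g(v) <= 1 + d(u)/R, R the geometric
# mean semi-axis.  Retries with halved magnitude if the mask collapses.
displaced_mask <- function(phantom, coeffs_mm, design, field = NULL) {
  dims <- design$dims
  field <- field %||% phantom_field(phantom, design)
  rbar <- prod(phantom$axes_mm)^(1 / 3)
  attempt <- 0
  repeat {
    d <- as.vector(field$Y %*% coeffs_mm)
    m <- array(field$g <= 1 + d / rbar, dims)
    if (any(m)) return(m)
    attempt <- attempt + 1
    if (attempt > 6)
      stop("observer displacement collapsed the mask", call. = FALSE)
    warning("displacement collapsed the mask; halving magnitude",
            call. = FALSE)
    coeffs_mm <- coeffs_mm / 2
  }
}

#' Simulate a manual delineation
#'
#' Deforms the ground-truth tumour boundary by a smooth random radial
#' displacement field (degree <= 2 spherical harmonics) with pointwise SD
#' `manual_boundary_sd`, composed of an observer-specific bias field
#' (fixed per observer across subjects and sessions) and an independent
#' per-session noise field, each carrying half the variance.  The result
#' is cleaned with [finalize_mask()], so it is a single connected mask.
#'
#' @param phantom a [generate_phantom()] result.
#' @param observer_id,session integer identifiers.
#' @param design the [study_design()].
#' @param boundary_sd displacement SD override, mm (defaults to
#'   `design$manual_boundary_sd`).
#' @param arm seed-stream tag so that manual and displacement-model
#'   semi-automatic observers draw independent noise.
#' @return a [segmentation_mask()] with `method = "manual"` (or the
#'   calling arm's method).
#' @export
simulate_manual_observer <- function(phantom, observer_id, session, design,
                                     boundary_sd = NULL, arm = "manual",
                                     field = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(design, "study_design"))
  if (!any(phantom$truth_mask$data)) stop("empty truth mask", call. = FALSE)
  sd_tot <- boundary_sd %||% design$manual_boundary_sd
  arm_tag <- if (arm == "manual") 0L else 5000L
  subj <- if (is.na(phantom$subject)) 0L else phantom$subject
  bias <- with_seed(derive_seed(design$rng_seed, 9001L + arm_tag,
                                observer_id),
                    stats::rnorm(9)) * (sd_tot / sqrt(2)) * sh_coeff_scale
  sess <- with_seed(derive_seed(design$rng_seed, 9002L + arm_tag, subj,
                                observer_id, session),
                    stats::rnorm(9)) * (sd_tot / sqrt(2)) * sh_coeff_scale
  m <- displaced_mask(phantom, bias + sess, design, field = field)
  out <- segmentation_mask(m, spacing = design$spacing, subject = subj,
                           method = if (arm == "manual") "manual"
                                    else "semiauto",
                           observer = observer_id, session = session)
  finalize_mask(out)
}

#' Simulate a semi-automatic (flood-fill) segmentation
#'
#' Places `design$n_seeds` seed voxels near the tumour centroid — jittered
#' by an observer-specific bias offset plus per-session noise, each with
#' SD `semiauto_seed_jitter_sd / sqrt(2)`, and clamped inside the tumour —
#' then runs [flood_fill()] on the noisy volume and cleans the result with
#' [finalize_mask()].  Deterministic for fixed identifiers.  Under
#' `design$semiauto_model = "displacement"` the arm instead uses the
#' manual observer model with `semiauto_boundary_sd`.
#'
#' @inheritParams simulate_manual_observer
#' @param flood_params optional [flood_fill_params()] override; the
#'   default uses `tolerance = design$flood_tolerance` (falling back to
#'   `contrast / 2`), faces-6 connectivity and
#'   `design$flood_neighborhood`.
#' @return a [segmentation_mask()] with `method = "semiauto"`.
#' @export
simulate_semiauto_observer <- function(phantom, observer_id, session, design,
                                       flood_params = NULL, field = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(design, "study_design"))
  if (design$semiauto_model == "displacement") {
    return(simulate_manual_observer(
      phantom, observer_id, session, design,
      boundary_sd = design$semiauto_boundary_sd, arm = "semiauto",
      field = field))
  }
  subj <- if (is.na(phantom$subject)) 0L else phantom$subject
  spacing <- design$spacing
  dims <- design$dims
  jsd <- design$semiauto_seed_jitter_sd / sqrt(2)
  bias <- with_seed(derive_seed(design$rng_seed, 9005L, observer_id),
                    stats::rnorm(3)) * jsd
  jit <- with_seed(derive_seed(design$rng_seed, 9006L, subj, observer_id,
                               session),
                   matrix(stats::rnorm(design$n_seeds * 3), ncol = 3)) * jsd
  centre <- phantom$center_mm
  truth <- phantom$truth_mask$data
  seeds <- matrix(NA_integer_, design$n_seeds, 3)
  for (s in seq_len(design$n_seeds)) {
    pos <- centre + bias + jit[s, ]
    for (iter in 0:25) {
      vox <- pmin(pmax(round(pos / spacing), 1L), dims)
      if (truth[vox[1], vox[2], vox[3]]) break
      pos <- centre + (pos - centre) * 0.8  # pull toward the centroid
    }
    if (!truth[vox[1], vox[2], vox[3]])
      stop("invalid seed: could not place seed inside the tumour",
           call. = FALSE)
    seeds[s, ] <- vox
  }
  params <- flood_params %||% flood_fill_params(
    tolerance = design$flood_tolerance %||% (design$contrast / 2),
    connectivity = 6L,
    neighborhood_size = design$flood_neighborhood)
  m <- flood_fill(phantom$volume, seeds, params)
  m$provenance <- list(subject = subj, method = "semiauto",
                       observer = observer_id, session = session)
  finalize_mask(m)
}

#' Generate the full synthetic segmentation study
#'
#' Creates one phantom per subject (the first `round(stage_split *
#' n_subjects)` subjects in Stages I-II, the rest in Stages III-IV) and
#' all manual and semi-automatic masks the design prescribes, each tagged
#' with subject/method/observer/session provenance.  Optionally persists
#' volumes and masks as NIfTI plus a JSON manifest.
#'
#' @param design a [study_design()].
#' @param dir optional output directory; when given, writes
#'   `volumes/sub-NNN.nii.gz`, `masks/sub-NNN_<method>_obsO_sessS.nii.gz`
#'   and `manifest.json`.
#' @return an object of class `radiomic_study`: `design`, `phantoms`
#'   (list), `masks` (list of [segmentation_mask()]), `manifest`
#'   (data.frame with subject, stage, diameter, method, observer,
#'   session and file paths when persisted).
#' @export
generate_study <- function(design, dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  n_low <- round(design$stage_split * design$n_subjects)
  phantoms <- vector("list", design$n_subjects)
  masks <- list()
  rows <- list()
  persist <- !is.null(dir)
  if (persist) {
    dir.create(file.path(dir, "volumes"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (subject in seq_len(design$n_subjects)) {
    group <- if (subject <= n_low) "I-II" else "III-IV"
    ph <- generate_phantom(group, design,
                           derive_seed(design$rng_seed, subject),
                           subject = subject)
    phantoms[[subject]] <- ph
    vol_path <- NA_character_
    if (persist) {
      vol_path <- file.path(dir, "volumes",
                            sprintf("sub-%03d.nii.gz", subject))
      write_volume(ph$volume, vol_path)
    }
    add_mask <- function(mask) {
      p <- mask$provenance
      path <- NA_character_
      if (persist) {
        path <- file.path(dir, "masks",
                          sprintf("sub-%03d_%s_obs%d_sess%d.nii.gz",
                                  subject, p$method, p$observer, p$session))
        write_mask(mask, path)
      }
      masks[[length(masks) + 1L]] <<- mask
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = subject, stage = group,
        tumour_diameter_cm = ph$tumour_diameter,
        method = p$method, observer = p$observer, session = p$session,
        volume_path = vol_path, mask_path = path,
        stringsAsFactors = FALSE)
    }
    field <- phantom_field(ph, design)  # shared by this subject's masks
    for (obs in seq_len(design$manual_observers))
      add_mask(simulate_manual_observer(ph, obs, 1L, design, field = field))
    for (obs in seq_len(design$semiauto_observers))
      for (sess in seq_len(design$semiauto_sessions))
        add_mask(simulate_semiauto_observer(ph, obs, sess, design,
                                            field = field))
  }
  manifest <- do.call(rbind, rows)
  if (persist) {
    jsonlite::write_json(
      list(design = unclass(design), manifest = manifest),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  structure(list(design = design, phantoms = phantoms, masks = masks,
                 manifest = manifest),
            class = "radiomic_study")
}

#' @export
print.radiomic_study <- function(x, ...) {
  cnt <- table(x$manifest$method)
  cat(sprintf("<radiomic_study> %d subjects, %d masks (%s)\n",
              x$design$n_subjects, nrow(x$manifest),
              paste(names(cnt), cnt, sep = ": ", collapse = ", ")))
  invisible(x)
}
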