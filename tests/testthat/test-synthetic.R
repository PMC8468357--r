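# Phantom generation and the simulated observer models.

test_that("mask counts follow the design formula for any design", {
  d1 <- study_design()
  expect_equal(unname(design_mask_counts(d1)), c(120, 120, 240))
  d2 <- study_design(n_subjects = 2L, manual_observers = 1L,
                     semiauto_observers = 1L, semiauto_sessions = 1L)
  expect_equal(unname(design_mask_counts(d2)), c(2, 2, 4))
  d3 <- study_design(n_subjects = 7L, manual_observers = 3L,
                     semiauto_observers = 2L, semiauto_sessions = 3L)
  expect_equal(unname(design_mask_counts(d3)), c(21, 42, 63))
  expect_error(study_design(n_subjects = 0L), "counts")
  expect_error(study_design(stage_split = 1.2), "stage_split")
  expect_error(study_design(noise_sd = -1), "standard deviations")
})

test_that("a generated study contains exactly the designed masks", {
  des <- tiny_design(2L)
  study <- suppressWarnings(generate_study(des))
  expect_length(study$masks, 3 * 4 + 3 * 2 * 2)
  expect_equal(sum(study$manifest$method == "manual"), 12)
  expect_equal(sum(study$manifest$method == "semiauto"), 12)
  # every mask tagged and nonempty
  for (m in study$masks) {
    expect_false(is.na(m$provenance$subject))
    expect_gt(sum(m$data), 0)
    expect_equal(count_components(m$data), 1)
  }
})

test_that("sampled diameters recover the group statistics within 3 SE", {
  des <- study_design(rng_seed = 123L)
  draws <- withr::with_seed(77, replicate(1000, sample_diameter("III-IV", des)))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 8.9), 3 * se)
  draws_low <- withr::with_seed(78, replicate(1000, sample_diameter("I-II", des)))
  expect_lt(abs(mean(draws_low) - 3.7), 3 * stats::sd(draws_low) / sqrt(1000))
  expect_lt(abs(stats::sd(draws_low) - 0.7), 0.1)
})

test_that("phantoms are deterministic under a fixed seed", {
  des <- tiny_design(5L)
  p1 <- generate_phantom("I-II", des, 101L, subject = 1L)
  p2 <- generate_phantom("I-II", des, 101L, subject = 1L)
  expect_identical(p1$volume$intensities, p2$volume$intensities)
  expect_identical(p1$truth_mask$data, p2$truth_mask$data)
  p3 <- generate_phantom("I-II", des, 102L, subject = 1L)
  expect_false(identical(p1$volume$intensities, p3$volume$intensities))
})

test_that("the noiseless phantom is exactly background plus contrast", {
  des <- tiny_design(7L, noise_sd = 0, background_texture_sd = 0)
  ph <- generate_phantom("I-II", des, 55L, subject = 1L)
  inside <- ph$truth_mask$data
  expect_true(all(ph$volume$intensities[inside] ==
                  des$background_level + des$contrast))
  expect_true(all(ph$volume$intensities[!inside] == des$background_level))
  expect_equal(count_components(inside), 1)
})

test_that("zero boundary noise reproduces the truth mask exactly", {
  des <- tiny_design(3L, manual_boundary_sd = 0)
  ph <- generate_phantom("I-II", des, 9L, subject = 1L)
  m <- simulate_manual_observer(ph, 1L, 1L, des)
  expect_identical(m$data, ph$truth_mask$data)
})

test_that("manual observers disagree when boundary noise is on", {
  des <- tiny_design(3L)
  ph <- generate_phantom("I-II", des, 9L, subject = 1L)
  m1 <- simulate_manual_observer(ph, 1L, 1L, des)
  m2 <- simulate_manual_observer(ph, 2L, 1L, des)
  expect_lt(dice(m1, m2), 1)
  expect_gt(dice(m1, m2), 0.2)  # deformed, not destroyed
})

test_that("mean Dice to truth decreases as manual boundary noise grows", {
  sds <- c(0.5, 1, 2, 4)
  mean_dice <- vapply(sds, function(s) {
    des <- tiny_design(11L, manual_boundary_sd = s)
    vals <- numeric(0)
    for (subj_seed in 1:8) {
      ph <- generate_phantom("I-II", des, 300L + subj_seed, subject = subj_seed)
      for (obs in 1:3)
        vals <- c(vals, dice(ph$truth_mask,
                             simulate_manual_observer(ph, obs, 1L, des)))
    }
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_dice) < 0))
})

test_that("ideal flood fill on a noiseless phantom recovers the truth", {
  des <- tiny_design(13L, noise_sd = 0, background_texture_sd = 0,
                     semiauto_seed_jitter_sd = 0)
  ph <- generate_phantom("I-II", des, 21L, subject = 1L)
  s <- simulate_semiauto_observer(ph, 1L, 1L, des)
  expect_identical(s$data, ph$truth_mask$data)
})

test_that("semi-automatic sessions differ but overlap more than manual observers", {
  # Monte-Carlo across phantoms: the structural asymmetry of the design
  des <- tiny_design(17L)
  d_semi <- d_man <- numeric(0)
  for (s in 1:10) {
    ph <- suppressWarnings(
      generate_phantom(if (s %% 2) "I-II" else "III-IV", des, 400L + s,
                       subject = s))
    s1 <- simulate_semiauto_observer(ph, 1L, 1L, des)
    s2 <- simulate_semiauto_observer(ph, 1L, 2L, des)
    m1 <- simulate_manual_observer(ph, 1L, 1L, des)
    m2 <- simulate_manual_observer(ph, 2L, 1L, des)
    d_semi <- c(d_semi, dice(s1, s2))
    d_man <- c(d_man, dice(m1, m2))
  }
  # sub-voxel seed jitter does not always move the seed voxels, so some
  # session pairs may coincide; across phantoms most must differ
  expect_gte(sum(d_semi < 1), 5)
  expect_gt(mean(d_semi), mean(d_man))
})

test_that("semi-automatic masks are deterministic per (observer, session)", {
  des <- tiny_design(19L)
  ph <- generate_phantom("I-II", des, 31L, subject = 1L)
  a <- simulate_semiauto_observer(ph, 2L, 1L, des)
  b <- simulate_semiauto_observer(ph, 2L, 1L, des)
  expect_identical(a$data, b$data)
})

test_that("regenerating a study under one seed gives identical masks and files", {
  des <- tiny_design(23L)
  s1 <- suppressWarnings(generate_study(des))
  s2 <- suppressWarnings(generate_study(des))
  for (i in seq_along(s1$masks))
    expect_identical(s1$masks[[i]]$data, s2$masks[[i]]$data)

  d1 <- tempfile(); d2 <- tempfile()
  suppressWarnings(generate_study(des, dir = d1))
  suppressWarnings(generate_study(des, dir = d2))
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  sums1 <- tools::md5sum(grep("masks/", f1, value = TRUE))
  sums2 <- tools::md5sum(grep("masks/", f2, value = TRUE))
  expect_identical(unname(sums1), unname(sums2))
  unlink(c(d1, d2), recursive = TRUE)
})
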