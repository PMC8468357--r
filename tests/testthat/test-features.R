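# Feature formulas per family against direct-summation oracles and
# closed-form degenerate cases.

test_that("first-order features on a constant region take degenerate values", {
  vol <- array(4, c(3, 3, 3))
  msk <- array(TRUE, c(3, 3, 3))
  d <- discretize(vol, msk)
  f <- first_order_features(vol[msk], d, voxel_volume = 2)
  expect_equal(f[["Mean"]], 4)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Entropy"]], 0, tolerance = 1e-12)
  expect_equal(f[["Uniformity"]], 1)
  expect_equal(f[["Energy"]], 27 * 16)
  expect_equal(f[["TotalEnergy"]], 2 * 27 * 16)
  expect_equal(f[["Skewness"]], 0)
  expect_equal(f[["Kurtosis"]], 0)
})

test_that("entropy of a uniform 8-bin histogram is 3 bits", {
  vol <- array(rep(0:7, 4), c(32, 1, 1))
  msk <- array(TRUE, c(32, 1, 1))
  d <- discretize(vol, msk, "fixed-bin-count", 8)
  f <- first_order_features(vol[msk], d, eps = 0)
  expect_equal(f[["Entropy"]], 3, tolerance = 1e-12)
  expect_equal(f[["Uniformity"]], 8 * (1 / 8)^2)
})

test_that("first-order features match the direct-summation oracle", {
  cases <- list(c(1, 2, 3, 4, 5),
                c(2.5, 2.5, 7, -1, 0.3, 12),
                withr::with_seed(3, stats::rnorm(40, 10, 4)))
  for (v in cases) {
    vol <- array(v, c(length(v), 1, 1))
    msk <- array(TRUE, dim(vol))
    d <- discretize(vol, msk, "fixed-bin-count", 4)
    p <- tabulate(d$levels[msk], 4) / length(v)
    f <- first_order_features(vol[msk], d, voxel_volume = 3.375)
    o <- first_order_oracle(v, p, voxel_volume = 3.375)
    for (nm in names(o))
      expect_equal(f[[nm]], o[[nm]], tolerance = 1e-12, info = nm)
  }
})

test_that("the 5-element fixture has its textbook order statistics", {
  v <- c(1, 2, 3, 4, 5)
  vol <- array(v, c(5, 1, 1)); msk <- array(TRUE, c(5, 1, 1))
  f <- first_order_features(v, discretize(vol, msk), voxel_volume = 1)
  expect_equal(f[["Median"]], 3)
  expect_equal(f[["Range"]], 4)
  expect_equal(f[["InterquartileRange"]], 2)   # type-7 quartiles 2 and 4
  expect_equal(f[["MeanAbsoluteDeviation"]], 1.2)
})

test_that("GLCM features: contrast, correlation and degenerate conventions", {
  const <- glcm(discretize(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3))))
  fc <- glcm_features(const)
  expect_equal(fc[["Contrast"]], 0)
  expect_equal(fc[["Correlation"]], 1)  # single level: perfectly dependent
  expect_equal(fc[["MCC"]], 1)

  strip <- discretize(array(c(0, 1, 0, 1), c(4, 1, 1)),
                      array(TRUE, c(4, 1, 1)), "fixed-bin-count", 2)
  fs <- glcm_features(glcm(strip, directions = matrix(c(1L, 0L, 0L), 1)))
  expect_equal(fs[["Contrast"]], 1.0)  # sum (i-j)^2 p = 1
  expect_equal(fs[["Correlation"]], -1, tolerance = 1e-12)  # anti-correlated

  # perfectly dependent two-level pattern: correlation 1
  blocks <- discretize(array(rep(c(0, 0, 9, 9), each = 4), c(4, 4, 1)),
                       array(TRUE, c(4, 4, 1)), "fixed-bin-count", 2)
  fb <- glcm_features(glcm(blocks, directions = matrix(c(1L, 0L, 0L), 1)))
  expect_equal(fb[["Correlation"]], 1, tolerance = 1e-12)
})

test_that("GLCM features stay within their analytic ranges on random input", {
  for (seed in 1:10) {
    fx <- random_masked_volume(c(5, 5, 5), seed, n_levels = 5)
    d <- discretize(fx$values, fx$mask, "fixed-bin-count", 5)
    f <- glcm_features(glcm(d))
    expect_gte(f[["Correlation"]], -1 - 1e-9)
    expect_lte(f[["Correlation"]], 1 + 1e-9)
    expect_gte(f[["Imc2"]], 0)
    expect_lte(f[["Imc2"]], 1)
    expect_gte(f[["MCC"]], 0)
    expect_lte(f[["MCC"]], 1 + 1e-9)
    expect_true(all(is.finite(f)))
  }
})

test_that("GLRLM features match direct evaluation on the tiny run matrix", {
  seq5 <- discretize(array(c(0, 0, 5, 5, 5), c(5, 1, 1)),
                     array(TRUE, c(5, 1, 1)), "fixed-bin-count", 2)
  r <- glrlm(seq5, directions = matrix(c(1L, 0L, 0L), 1))
  f <- glrlm_features(r)
  # r(1,2) = 1, r(2,3) = 1; Nr = 2, Np = 5
  expect_equal(f[["RunPercentage"]], 0.4)
  expect_equal(f[["ShortRunEmphasis"]], (1 / 4 + 1 / 9) / 2)
  expect_equal(f[["LongRunEmphasis"]], (4 + 9) / 2)
  expect_equal(f[["GrayLevelNonUniformity"]], (1 + 1) / 2)
  expect_equal(f[["HighGrayLevelRunEmphasis"]], (1 + 4) / 2)
  expect_equal(f[["LowGrayLevelRunEmphasis"]], (1 + 1 / 4) / 2)
  expect_equal(f[["RunEntropy"]], 1, tolerance = 1e-9)  # two equal runs
  expect_equal(f[["LongRunHighGrayLevelEmphasis"]], (1 * 4 + 4 * 9) / 2)
})

test_that("GLDM features match direct evaluation on small fixtures", {
  d2 <- gldm(discretize(array(c(0, 0, 9, 9), c(2, 2, 1)),
                        array(TRUE, c(2, 2, 1)), "fixed-bin-count", 2), 0, 1)
  f <- gldm_features(d2)
  # d(1, j=2) = 2, d(2, j=2) = 2 with the j = dependence + 1 offset
  expect_equal(f[["SmallDependenceEmphasis"]], (2 / 4 + 2 / 4) / 4)
  expect_equal(f[["LargeDependenceEmphasis"]], (2 * 4 + 2 * 4) / 4)
  expect_equal(f[["GrayLevelNonUniformity"]], (4 + 4) / 4)
  expect_equal(f[["DependenceNonUniformity"]], 16 / 4)
  expect_equal(f[["HighGrayLevelEmphasis"]], (2 + 8) / 4)
  expect_equal(f[["DependenceEntropy"]], 1, tolerance = 1e-9)
})

test_that("feature family sizes are 18, 24, 16 and 14", {
  fx <- random_masked_volume(c(5, 5, 5), 1, n_levels = 4)
  d <- discretize(fx$values, fx$mask, "fixed-bin-count", 4)
  expect_length(first_order_features(fx$values[fx$mask], d), 18)
  expect_length(glcm_features(glcm(d)), 24)
  expect_length(glrlm_features(glrlm(d)), 16)
  expect_length(gldm_features(gldm(d)), 14)
})
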