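# ANOVA decomposition, ICC estimators, banding and the rank-sum comparison.

test_that("ANOVA mean squares match textbook aov() on fixed and random fixtures", {
  fixt <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), 4, 2)  # [[1,2],[3,4],[5,6],[7,8]]
  a <- anova_decompose(fixt)
  o <- anova_oracle(fixt)
  expect_equal(a$ms_rows, o$ms_rows, tolerance = 1e-10)
  expect_equal(a$ms_cols, o$ms_cols, tolerance = 1e-10)
  expect_equal(a$ms_error, o$ms_error, tolerance = 1e-10)
  expect_equal(a$ms_within, o$ms_within, tolerance = 1e-10)

  # additive column shift: MS_C changes, MS_R and MS_E do not
  shifted <- sweep(fixt, 2, c(0, 10), "+")
  a2 <- anova_decompose(shifted)
  expect_equal(a2$ms_rows, a$ms_rows, tolerance = 1e-12)
  expect_equal(a2$ms_error, a$ms_error, tolerance = 1e-12)
  expect_gt(a2$ms_cols, a$ms_cols)

  # all cells equal -> every mean square zero
  z <- anova_decompose(matrix(5, 3, 3))
  expect_equal(c(z$ms_rows, z$ms_cols, z$ms_error, z$ms_within),
               rep(0, 4))

  # sum-of-squares identity: SS_tot = (n-1) MS_R + n(k-1) MS_W
  for (seed in 1:20) {
    x <- withr::with_seed(seed, matrix(stats::rnorm(24), 6, 4))
    d <- anova_decompose(x)
    expect_equal((6 - 1) * d$ms_rows + 6 * (4 - 1) * d$ms_within,
                 sum((x - mean(x))^2), tolerance = 1e-9)
  }

  expect_error(anova_decompose(matrix(1:3, 3, 1)), "insufficient design")
})

test_that("both ICC estimators match independent oracles on 200 random matrices", {
  for (seed in 1:200) {
    x <- withr::with_seed(seed, {
      n <- sample(3:10, 1); k <- sample(2:5, 1)
      matrix(stats::rnorm(n * k, sd = sample(c(0.5, 1, 5), 1)) +
               rep(stats::rnorm(n, sd = 2), k), n, k)
    })
    expect_equal(icc_agreement(x)$value, icc_a1_oracle(x),
                 tolerance = 1e-10, info = paste("A1 seed", seed))
    expect_equal(icc_agreement(x)$value, icc_a1_oracle2(x),
                 tolerance = 1e-10, info = paste("A1b seed", seed))
    expect_equal(icc_consistency(x)$value, icc_c1_oracle(x),
                 tolerance = 1e-10, info = paste("C1 seed", seed))
  }
})

test_that("perfect agreement gives exactly 1; noisy raters of equal subjects give <= 0", {
  x <- matrix(rep(c(2, 9, 4, 7, 5), 3), 5, 3)
  expect_identical(icc_agreement(x)$value, 1)
  expect_identical(icc_consistency(x)$value, 1)

  # no subject signal, pure rater noise
  y <- withr::with_seed(5, matrix(stats::rnorm(20), 5, 4))
  y <- y - rowMeans(y) + 3  # remove subject variance entirely
  expect_lte(icc_agreement(y)$value, 0)
})

test_that("per-rater offsets: consistency stays 1, agreement drops below 1", {
  x <- matrix(c(1, 3, 5, 7, 9, 1, 3, 5, 7, 9), 5, 2)
  shifted <- sweep(x, 2, c(0, 4), "+")
  expect_equal(icc_consistency(shifted)$value, 1, tolerance = 1e-12)
  expect_lt(icc_agreement(shifted)$value, 1)
  expect_gt(icc_agreement(x)$value - icc_agreement(shifted)$value, 0)
})

test_that("undefined ICC is an error when strict, NA otherwise", {
  flat <- matrix(1, 4, 3)
  expect_error(icc_agreement(flat), "undefined ICC")
  expect_true(is.na(icc_agreement(flat, strict = FALSE)$value))
})

test_that("reproducibility bands partition (-Inf, 1] with exact thresholds", {
  expect_identical(classify_icc(0.8), "high")
  expect_identical(classify_icc(0.5), "medium")
  expect_identical(classify_icc(-0.1), "low")
  expect_identical(classify_icc(0.79999), "medium")
  expect_identical(classify_icc(0.49999), "low")
  expect_identical(classify_icc(1), "high")
  # exhaustive and disjoint over a grid
  g <- classify_icc(seq(-2, 1, by = 0.01))
  expect_true(all(g %in% c("high", "medium", "low")))
  expect_error(classify_icc(1.5))
})

test_that("rank-sum: exact enumeration, tie convention, approximation quality", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)  # most extreme of C(6,3) = 20 arrangements
  expect_equal(w$p_value, wilcoxon_exact_oracle(c(1, 2, 3), c(4, 5, 6)))

  expect_gt(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))$p_value, 1)

  # continuity-corrected normal approximation tracks the exact tail
  for (seed in 1:5) {
    ab <- withr::with_seed(seed, list(a = stats::rnorm(10),
                                      b = stats::rnorm(10, 0.5)))
    p_apx <- wilcoxon_rank_sum(ab$a, ab$b, exact = FALSE)$p_value
    p_ex <- wilcoxon_rank_sum(ab$a, ab$b, exact = TRUE)$p_value
    expect_lt(abs(p_apx - p_ex), 0.02)
  }
})

test_that("variance-components simulation recovers the theoretical ICC(A,1)", {
  sg2 <- 4; sr2 <- 0.5; se2 <- 1
  theo <- sg2 / (sg2 + sr2 + se2)
  # n large enough that the O(1/n) small-sample bias of the single-rater
  # agreement estimator is negligible against the Monte-Carlo error
  n <- 50; k <- 4
  vals <- withr::with_seed(99, replicate(1000, {
    subj <- stats::rnorm(n, sd = sqrt(sg2))
    rater <- stats::rnorm(k, sd = sqrt(sr2))
    x <- outer(subj, rater, `+`) + matrix(stats::rnorm(n * k, sd = sqrt(se2)),
                                          n, k)
    icc_agreement(x)$value
  }))
  se_mc <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - theo), 3 * se_mc)
})
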