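# Discretization and the three texture matrices against brute-force
# pairwise/run/neighbourhood enumeration oracles.

test_that("discretization maps ranges to levels as specified", {
  vals <- array(0:31, c(32, 1, 1))
  m <- array(TRUE, c(32, 1, 1))
  d <- discretize(vals, m, "fixed-bin-count", 32)
  expect_equal(d$levels[m], 1:32)
  expect_equal(d$ng, 32)

  const <- discretize(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)),
                      "fixed-bin-count", 8)
  expect_true(all(const$levels[const$mask] == 1))
  expect_equal(const$ng, 1)

  # hand-evaluated floor formula for fixed bin width
  vw <- array(c(1.0, 2.5, 7.9), c(3, 1, 1))
  dw <- discretize(vw, array(TRUE, c(3, 1, 1)), "fixed-bin-width", 2)
  expect_equal(dw$levels[, 1, 1], c(1L, 1L, 4L))

  expect_error(discretize(vals, array(FALSE, c(32, 1, 1))), "empty mask")
})

test_that("there are exactly 13 unique distance-1 directions in 3D", {
  dirs <- texture_directions()
  expect_equal(nrow(dirs), 13)
  # together with their negations they cover all 26 neighbours
  all26 <- rbind(dirs, -dirs)
  expect_equal(nrow(unique(all26)), 26)
})

test_that("GLCM: constant block, alternating strip, and normalization", {
  const <- discretize(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  g <- glcm(const)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)

  # alternating 1,2,1,2 strip: 3 symmetric pairs each way
  strip <- discretize(array(c(0, 1, 0, 1), c(4, 1, 1)),
                      array(TRUE, c(4, 1, 1)), "fixed-bin-count", 2)
  gs <- glcm(strip, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(gs$counts_per_direction[[1]],
               matrix(c(0, 3, 3, 0), 2, 2))
  expect_equal(gs$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("GLCM equals the pairwise-enumeration oracle on random volumes", {
  for (seed in 1:6) {
    fx <- random_masked_volume(c(5, 4, 6), seed)
    d <- discretize(fx$values, fx$mask, "fixed-bin-count", 4)
    g <- glcm(d)
    dirs <- texture_directions()
    for (r in c(1, 5, 13)) {
      oracle <- glcm_oracle_direction(d$levels, fx$mask, dirs[r, ])
      expect_equal(g$counts_per_direction[[r]], oracle,
                   info = paste("seed", seed, "dir", r))
    }
    # aggregate equals the mean of the per-direction normalized matrices
    has <- vapply(g$counts_per_direction, function(m) sum(m) > 0, logical(1))
    expect_equal(g$p, Reduce(`+`, g$per_direction[has]) / sum(has),
                 tolerance = 1e-14)
    expect_equal(sum(g$p), 1, tolerance = 1e-12)
  }
})

test_that("GLRLM decomposes runs correctly and conserves voxel counts", {
  # 1,1,2,2,2 along x
  seq5 <- discretize(array(c(0, 0, 5, 5, 5), c(5, 1, 1)),
                     array(TRUE, c(5, 1, 1)), "fixed-bin-count", 2)
  r <- glrlm(seq5, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(r$counts[1, 2], 1)
  expect_equal(r$counts[2, 3], 1)
  expect_equal(sum(r$counts), 2)
  # conservation: sum l * r(i, l) = 5
  lmat <- matrix(seq_len(ncol(r$counts)), nrow(r$counts), ncol(r$counts),
                 byrow = TRUE)
  expect_equal(sum(lmat * r$counts), 5)

  # constant line -> one run of full length
  line <- discretize(array(1, c(7, 1, 1)), array(TRUE, c(7, 1, 1)))
  rl <- glrlm(line, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(rl$counts[1, 7], 1)
  expect_equal(sum(rl$counts), 1)
})

test_that("GLRLM matches the line-walking oracle and conserves per direction", {
  for (seed in 1:6) {
    fx <- random_masked_volume(c(5, 5, 4), seed, n_levels = 3)
    d <- discretize(fx$values, fx$mask, "fixed-bin-count", 3)
    r <- glrlm(d)
    dirs <- texture_directions()
    n_masked <- sum(fx$mask)
    for (k in c(2, 7, 11)) {
      oracle <- glrlm_oracle_direction(d$levels, fx$mask, dirs[k, ])
      got <- r$per_direction[[k]]
      expect_equal(got[, seq_len(ncol(oracle)), drop = FALSE][
        seq_len(nrow(oracle)), , drop = FALSE], oracle,
        info = paste("seed", seed, "dir", k))
      lmat <- matrix(seq_len(ncol(got)), nrow(got), ncol(got), byrow = TRUE)
      expect_equal(sum(lmat * got), n_masked,
                   info = paste("conservation seed", seed, "dir", k))
    }
  }
})

test_that("GLDM counts dependence as specified", {
  # constant 3x3x3: centre voxel has all 26 neighbours dependent
  const <- discretize(array(1, c(3, 3, 3)), array(TRUE, c(3, 3, 3)))
  d <- gldm(const, alpha = 0, delta = 1)
  expect_equal(sum(d$counts), 27)
  expect_equal(d$counts[1, 27], 1)  # dependence 26 -> column 27

  # single masked voxel -> dependence 0
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  d1 <- gldm(discretize(array(4, c(3, 3, 3)), m1), 0, 1)
  expect_equal(d1$counts[1, 1], 1)
  expect_equal(sum(d1$counts), 1)

  # 2x2x1 with levels 1,1,2,2: every voxel has exactly 1 dependent neighbour
  d2 <- gldm(discretize(array(c(0, 0, 9, 9), c(2, 2, 1)),
                        array(TRUE, c(2, 2, 1)), "fixed-bin-count", 2), 0, 1)
  expect_equal(d2$counts[1, 2], 2)
  expect_equal(d2$counts[2, 2], 2)
})

test_that("GLDM matches the neighbourhood-enumeration oracle", {
  for (seed in 1:6) {
    fx <- random_masked_volume(c(4, 5, 4), seed, n_levels = 3)
    d <- discretize(fx$values, fx$mask, "fixed-bin-count", 3)
    for (alpha in c(0, 1)) {
      got <- gldm(d, alpha = alpha, delta = 1)
      oracle <- gldm_oracle(d$levels, fx$mask, alpha, 1)
      expect_equal(got$counts[seq_len(nrow(oracle)),
                              seq_len(ncol(oracle)), drop = FALSE],
                   oracle, info = paste("seed", seed, "alpha", alpha))
      expect_equal(sum(got$counts), sum(fx$mask))
    }
  }
})
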