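# Seeded flood-fill segmentation and mask finalization.

test_that("uniform volume floods completely; two-region volume stays put", {
  v <- volume3d(array(7, c(5, 5, 5)))
  m <- flood_fill(v, c(3, 3, 3), flood_fill_params(tolerance = 0))
  expect_equal(sum(m$data), 125)

  a <- array(0, c(6, 4, 4))
  a[4:6, , ] <- 100
  v2 <- volume3d(a)
  m2 <- flood_fill(v2, c(1, 1, 1), flood_fill_params(tolerance = 10))
  expect_equal(which(m2$data), which(a == 0))
  m3 <- flood_fill(v2, c(5, 2, 2), flood_fill_params(tolerance = 10))
  expect_equal(which(m3$data), which(a == 100))
})

test_that("neighbourhood-size leak check blocks a one-voxel bridge", {
  # two 3x3 plates joined by a single-voxel bridge; per-voxel tolerance
  # admits both, the neighbourhood mean around the bridge does not
  a <- array(0, c(7, 7, 3))
  a[1:3, 3:5, 2] <- 50
  a[5:7, 3:5, 2] <- 50
  a[4, 4, 2] <- 50
  v <- volume3d(a)
  no_check <- flood_fill(v, c(2, 4, 2), flood_fill_params(tolerance = 36))
  expect_equal(sum(no_check$data), 19)  # both plates + bridge
  checked <- flood_fill(v, c(2, 4, 2),
                        flood_fill_params(tolerance = 36,
                                          neighborhood_size = 1))
  oracle <- flood_oracle(a, c(2, 4, 2), tol = 36, neighborhood = 1)
  expect_equal(checked$data, oracle)
  expect_true(sum(checked$data) < 19)
  expect_false(checked$data[4, 4, 2])       # bridge rejected
  expect_false(any(checked$data[5:7, , ]))  # far plate not reached
})

test_that("flood fill matches a stack-based oracle on random volumes", {
  for (seed in 1:8) {
    fx <- random_masked_volume(c(6, 5, 4), seed, n_levels = 3)
    vol <- fx$values * 10
    seedv <- c(3, 3, 2)
    for (conn in c(6L, 18L, 26L)) {
      m <- flood_fill(volume3d(vol), seedv,
                      flood_fill_params(tolerance = 5, connectivity = conn,
                                        reference_mode = "seed-intensity"))
      o <- flood_oracle(vol, seedv, tol = 5, connectivity = conn)
      expect_equal(m$data, o, info = paste("seed", seed, "conn", conn))
    }
  }
})

test_that("flood fill is invariant to seed ordering and includes all seeds", {
  fx <- random_masked_volume(c(6, 6, 6), 42, n_levels = 5)
  vol <- fx$values * 7
  seeds <- rbind(c(2, 2, 2), c(5, 5, 5), c(3, 4, 2))
  p <- flood_fill_params(tolerance = 10)
  m1 <- flood_fill(volume3d(vol), seeds, p)
  m2 <- flood_fill(volume3d(vol), seeds[c(3, 1, 2), ], p)
  expect_identical(m1$data, m2$data)
  for (r in seq_len(nrow(seeds)))
    expect_true(m1$data[seeds[r, 1], seeds[r, 2], seeds[r, 3]])
})

test_that("increasing tolerance never shrinks the mask", {
  fx <- random_masked_volume(c(7, 7, 7), 9, n_levels = 6)
  vol <- fx$values * 3
  prev <- 0
  for (tol in c(0, 3, 6, 9, 15)) {
    m <- flood_fill(volume3d(vol), c(4, 4, 4),
                    flood_fill_params(tolerance = tol,
                                      reference_mode = "seed-intensity"))
    expect_gte(sum(m$data), prev)
    prev <- sum(m$data)
  }
})

test_that("seed validation and the voxel cap raise informative errors", {
  v <- volume3d(array(1, c(4, 4, 4)))
  expect_error(flood_fill(v, c(9, 1, 1), flood_fill_params(tolerance = 1)),
               "invalid seed")
  expect_error(flood_fill(v, c(2, 2, 2),
                          flood_fill_params(tolerance = 1, max_voxels = 10)),
               "max_voxels")
})

test_that("finalize_mask keeps the largest component and fills holes", {
  # solid ball: idempotent
  ball <- segmentation_mask(rasterized_ball(6))
  expect_identical(finalize_mask(ball)$data, ball$data)

  # ball plus a disjoint speck: speck removed
  speck <- ball
  speck$data[1, 1, 1] <- TRUE
  expect_identical(finalize_mask(speck)$data, ball$data)

  # hollow shell: cavity filled; final count = shell + cavity
  shell <- array(FALSE, c(11, 11, 11))
  shell[3:9, 3:9, 3:9] <- TRUE
  cavity <- array(FALSE, c(11, 11, 11))
  cavity[5:7, 5:7, 5:7] <- TRUE
  hollow <- shell & !cavity
  fixed <- finalize_mask(segmentation_mask(hollow))
  expect_equal(sum(fixed$data), sum(shell))
  expect_equal(count_components(fixed$data), 1)
  # idempotence
  expect_identical(finalize_mask(fixed)$data, fixed$data)

  expect_error(finalize_mask(segmentation_mask(array(FALSE, c(3, 3, 3)))),
               "empty")
})
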