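test_that("COP is the pressure-weighted centroid with 0-based coordinates", {
  # point mass
  v <- point_video(cbind(5, 2), 3.2)
  ct <- cop_trajectory(v)
  expect_equal(ct$x, 2)
  expect_equal(ct$y, 5)
  expect_true(ct$defined)

  # uniform field on 20 x 7: centroid (3, 9.5)
  u <- pressure_video(array(1, dim = c(20, 7, 1)))
  ctu <- cop_trajectory(u)
  expect_equal(c(ctu$x, ctu$y), c(3, 9.5))

  # weighted mean: pressures 1 at x=0 and 3 at x=4 on one row -> x = 3
  v2 <- point_video(cbind(c(0, 0), c(0, 4)), c(1, 3))
  ct2 <- cop_trajectory(v2)
  expect_equal(ct2$x, 3)
  expect_equal(ct2$y, 0)

  # zero-pressure frame is undefined
  z <- pressure_video(array(0, dim = c(4, 4, 2)))
  expect_false(any(cop_trajectory(z)$defined))
})

test_that("masking keeps covered cells and ignores duplicates", {
  v <- random_video(h = 6, w = 5, n = 3, seed = 2)
  full <- placement(counts = matrix(1, 6, 5), n_sensors = 30)
  expect_equal(apply_mask(v, full)$frames, v$frames)

  empty <- placement(grid = c(6, 5))
  expect_true(all(apply_mask(v, empty)$frames == 0))

  one <- placement(cbind(2, 3), grid = c(6, 5), n_sensors = 8)
  two <- placement(rbind(c(2, 3), c(2, 3)), grid = c(6, 5), n_sensors = 8)
  expect_identical(apply_mask(v, one)$frames, apply_mask(v, two)$frames)

  expect_error(apply_mask(v, placement(grid = c(4, 4))), "mismatch")
})

test_that("episode reward matches the closed-form single-frame oracle", {
  # two equal pressures at (y=10,x=3) and (y=6,x=3): COP (3, 8); one sensor
  # at (3,10) leaves the masked COP at (3,10), distance 2
  v <- point_video(rbind(c(10, 3), c(6, 3)), c(2, 2))
  p <- placement(cbind(10, 3), grid = c(20, 7), n_sensors = 8)
  maxd <- sqrt(20^2 + 7^2)
  expect_equal(episode_reward(v, p), (1 - 2 / maxd)^0.4, tolerance = 1e-12)
  expect_equal((1 - 2 / maxd)^0.4, 0.9611, tolerance = 1e-4)

  # full coverage -> 1; empty placement -> 0
  expect_equal(episode_reward(v, placement(counts = matrix(1, 20, 7),
                                           n_sensors = 140)), 1)
  expect_equal(episode_reward(v, placement(grid = c(20, 7))), 0)
})

test_that("undefined-COP frames follow the skip / max-distance conventions", {
  # frame 1 loaded, frame 2 empty: empty frame is excluded from the mean
  f1 <- matrix(0, 4, 4); f1[2, 2] <- 1
  v <- pressure_video(list(f1, matrix(0, 4, 4)))
  p_cover <- placement(cbind(1, 1), grid = c(4, 4), n_sensors = 2)
  expect_equal(episode_reward(v, p_cover), 1)

  # masked-undefined (sensor on a dead cell) costs maxdistance on that frame
  p_off <- placement(cbind(0, 0), grid = c(4, 4), n_sensors = 2)
  expect_equal(episode_reward(v, p_off), 0)

  # all frames empty -> error
  z <- pressure_video(array(0, dim = c(4, 4, 2)))
  expect_error(episode_reward(z, p_cover), "no defined COP frames")
})

test_that("episode reward stays within [0, 1] on random inputs", {
  for (seed in 1:20) {
    v <- random_video(h = 8, w = 5, n = 4, seed = seed)
    cells <- withr::with_seed(seed, {
      cbind(sample(0:7, 3, TRUE), sample(0:4, 3, TRUE))
    })
    p <- placement(cells, grid = c(8, 5), n_sensors = 3)
    r <- episode_reward(v, p)
    expect_gte(r, 0)
    expect_lte(r, 1)
  }
})

test_that("redistributed rewards telescope exactly to the episode reward", {
  for (seed in 1:10) {
    v <- random_video(h = 8, w = 5, n = 4, seed = seed + 100)
    actions <- withr::with_seed(seed, sample(0:39, 8, TRUE))
    r <- redistribute_rewards(v, actions)
    final <- episode_reward(v, placement(actions, grid = c(8, 5),
                                         n_sensors = 8))
    expect_equal(sum(r), final, tolerance = 1e-12)
  }
})

test_that("duplicate actions earn zero and negative steps are possible", {
  v <- point_video(rbind(c(10, 3), c(6, 3)), c(2, 2))
  r <- redistribute_rewards(v, c(73L, 73L))  # (y=10,x=3) twice
  expect_gt(r[1], 0)
  expect_identical(r[2], 0)

  # covering the far cell first then a skewing cell can reduce the fit
  r2 <- redistribute_rewards(v, c(73L, 45L, 73L))  # (10,3), (6,3), dup
  expect_equal(sum(r2), 1)  # both loaded cells covered -> perfect fit

  # a negative per-step reward occurs when added mass worsens the masked COP:
  # cover the near-centroid cell first, then a heavy far-corner cell
  v3 <- point_video(rbind(c(0, 0), c(19, 6), c(10, 3)), c(5, 5, 0.2))
  rr <- redistribute_rewards(v3, c(73L, 0L))
  expect_gt(rr[1], 0)
  expect_lt(rr[2], 0)
})

test_that("placement json round-trips and validates", {
  p <- placement(rbind(c(1, 2), c(1, 2), c(7, 0)), grid = c(20, 7),
                 n_sensors = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_placement(p, path)
  q <- read_placement(path, n_sensors = 8)
  expect_identical(q$counts, p$counts)
  expect_error(placement(cbind(25, 2), grid = c(20, 7)), "out of grid")
  expect_error(placement(rep(0L, 9), grid = c(20, 7), n_sensors = 8),
               "budget")
})
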