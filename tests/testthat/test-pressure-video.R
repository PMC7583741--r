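test_that("constructor enforces the video invariants", {
  expect_s3_class(pressure_video(array(0, dim = c(2, 2, 1))), "pressure_video")
  expect_error(pressure_video(list()), "no frames")
  expect_error(pressure_video(array(-1, dim = c(2, 2, 1))), "negative")
  expect_error(pressure_video(list(matrix(0, 2, 2), matrix(0, 3, 2))), "shape")
  expect_error(pressure_video(array(0, dim = c(2, 2, 1)), frame_rate = 0))
})

test_that("ppv round trip is bitwise lossless", {
  v <- pressure_video(array(c(0, 0, 0, 0), dim = c(2, 2, 1)))
  path <- withr::local_tempfile(fileext = ".ppv")
  write_video(v, path)
  expect_identical(read_video(path)$frames, v$frames)

  # random 7x20-style videos round-trip exactly, including awkward decimals
  for (seed in 1:5) {
    v <- random_video(h = 20, w = 7, n = 3, seed = seed)
    v$frames[1, 1, 1] <- 1 / 3
    v$frames[2, 2, 1] <- pi * 1e-7
    write_video(v, path)
    r <- read_video(path)
    expect_identical(r$frames, v$frames)
    expect_identical(r$frame_rate, v$frame_rate)
    expect_identical(r$cell_area, v$cell_area)
  }
})

test_that("malformed files produce informative parse errors", {
  path <- withr::local_tempfile(fileext = ".ppv")
  writeLines(character(0), path)
  expect_error(read_video(path), "no frames")

  writeLines(c("ppv 2 2 100", "1 2", "3"), path)
  expect_error(read_video(path), "frame 1.*ragged|ragged")

  writeLines(c("ppv 2 2 100", "1 2", "3 -4"), path)
  expect_error(read_video(path), "negative")

  expect_error(read_video(file.path(tempdir(), "absent.ppv")), "no such file")
})

test_that("csv directories read as one frame per file", {
  dir <- withr::local_tempdir()
  write.table(matrix(c(1, 2, 3, 4), 2, 2), file.path(dir, "f01.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(matrix(0, 2, 2), file.path(dir, "f02.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  v <- read_video(dir)
  expect_equal(n_frames(v), 2)
  expect_equal(v$frames[, , 1], matrix(c(1, 2, 3, 4), 2, 2))
})

test_that("stance splitting finds maximal loaded runs and preserves frames", {
  z <- matrix(0, 2, 2)
  mk <- function(tot) {
    f <- z; f[1, 1] <- tot; f
  }
  v <- pressure_video(list(mk(0), mk(5), mk(7), mk(0), mk(0), mk(3), mk(0)))
  segs <- split_stance_phases(v)
  expect_length(segs, 2)
  expect_equal(vapply(segs, n_frames, integer(1)), c(2L, 1L))
  expect_equal(frame_totals(segs[[1]]), c(5, 7))
  expect_equal(frame_totals(segs[[2]]), 3)

  # concatenating outputs plus zero frames reconstructs the input multiset
  kept <- unlist(lapply(segs, frame_totals))
  expect_setequal(c(kept, rep(0, 4)), frame_totals(v))

  expect_length(split_stance_phases(pressure_video(list(z, z))), 0)
  expect_length(split_stance_phases(pressure_video(list(mk(1)))), 1)
})

test_that("representative selection groups contiguously and reproducibly", {
  segs <- split_stance_phases(pressure_video(lapply(1:24, function(i) {
    m <- matrix(0, 2, 2); if (i %% 2 == 0) m[1, 1] <- i; m
  })))
  expect_length(segs, 12)

  # 12 segments over 5 groups: sizes 3,3,2,2,2, one pick per group
  sel <- select_representatives(segs, n_groups = 5, seed = 7)
  expect_length(sel, 5)
  src <- vapply(sel, function(s) s$segment, integer(1))
  bounds <- c(0, cumsum(c(3, 3, 2, 2, 2)))
  for (g in 1:5) {
    expect_gt(src[g], bounds[g])
    expect_lte(src[g], bounds[g + 1])
  }
  sel2 <- select_representatives(segs, n_groups = 5, seed = 7)
  expect_identical(vapply(sel2, function(s) s$segment, integer(1)), src)

  # exactly n_groups segments: identity selection
  sel3 <- select_representatives(segs[1:5], n_groups = 5, seed = 1)
  expect_identical(vapply(sel3, function(s) s$segment, integer(1)),
                   vapply(segs[1:5], function(s) s$segment, integer(1)))
  expect_error(select_representatives(segs[1:4], n_groups = 5, seed = 1),
               "at least 5")
})

test_that("border cropping takes the union bounding box and is idempotent", {
  f1 <- matrix(0, 4, 4); f1[2:3, 2:3] <- 1
  v <- pressure_video(list(f1, f1))
  cv <- crop_white_border(v)
  expect_equal(grid_dim(cv), c(2L, 2L))

  # a frame touching every border row/col leaves the video unchanged
  f2 <- matrix(1, 4, 4)
  v2 <- pressure_video(list(f2))
  expect_identical(crop_white_border(v2)$frames, v2$frames)

  # union over frames: row 0 loaded in frame A, row 3 in frame B -> keep all
  fa <- matrix(0, 4, 4); fa[1, 2] <- 1
  fb <- matrix(0, 4, 4); fb[4, 2] <- 1
  v3 <- crop_white_border(pressure_video(list(fa, fb)))
  expect_equal(grid_dim(v3), c(4L, 1L))

  # idempotence
  expect_identical(crop_white_border(cv)$frames, cv$frames)
  expect_error(crop_white_border(pressure_video(list(matrix(0, 2, 2)))),
               "nothing to crop")
})

test_that("downsampling conserves force and fixes uniform fields", {
  # hand-computed area-weighted mean: 2x2 [[1,3],[2,4]] -> 1x1 value 2.5
  v <- pressure_video(array(c(1, 3, 2, 4), dim = c(2, 2, 1)))
  d <- downsample_video(v, c(1, 1))
  expect_equal(d$frames[1, 1, 1], 2.5)
  expect_equal(d$cell_area, 4)

  # uniform pressure stays uniform at any ratio, including non-integer
  u <- pressure_video(array(3.7, dim = c(21, 10, 2)))
  du <- downsample_video(u, c(20, 7))
  expect_equal(as.vector(du$frames), rep(3.7, 20 * 7 * 2), tolerance = 1e-12)

  # identity when shapes already match
  v7 <- random_video(h = 20, w = 7, n = 2, seed = 3)
  expect_equal(downsample_video(v7, c(20, 7))$frames, v7$frames,
               tolerance = 1e-12)

  # force conservation for random videos and awkward ratios
  for (seed in 1:4) {
    v <- random_video(h = 13, w = 5, n = 3, seed = seed)
    d <- downsample_video(v, c(20, 7))
    f_in <- frame_totals(v) * v$cell_area
    f_out <- frame_totals(d) * d$cell_area
    expect_equal(f_out, f_in, tolerance = 1e-9)
    expect_true(all(d$frames >= 0))
  }
})

test_that("the full preprocessing pipeline emits stance videos on the target grid", {
  # build a long recording: 9 stances of varying footprint sizes
  frames <- list()
  withr::with_seed(42, {
    for (s in 1:9) {
      for (k in 1:3) {
        f <- matrix(0, 21, 10)
        f[3:15, 3:8] <- stats::runif(13 * 6)
        frames <- c(frames, list(f))
      }
      frames <- c(frames, list(matrix(0, 21, 10)))
    }
  })
  rec <- pressure_video(frames)
  out <- preprocess_video(rec, n_groups = 5, target = c(20, 7), seed = 3)
  expect_length(out, 5)
  for (v in out) {
    expect_equal(grid_dim(v), c(20L, 7L))
    expect_true(all(frame_totals(v) > 0))
  }
})
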