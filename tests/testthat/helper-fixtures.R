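# Small fixture builders used across test files.

# Random non-negative video with a seeded generator.
random_video <- function(h = 7, w = 4, n = 3, seed = 1, sparsity = 0.5) {
  withr::with_seed(seed, {
    frames <- array(stats::runif(h * w * n) *
                      (stats::runif(h * w * n) > sparsity),
                    dim = c(h, w, n))
  })
  pressure_video(frames)
}

# Single-frame video with pressures at given 0-based (y, x) cells.
point_video <- function(cells, values, grid = c(20, 7)) {
  f <- matrix(0, grid[1], grid[2])
  for (i in seq_len(nrow(cells))) {
    f[cells[i, 1] + 1, cells[i, 2] + 1] <- values[i]
  }
  pressure_video(array(f, dim = c(grid, 1)))
}

# A tiny deterministic environment: 2 x 2 grid, single frame, 1 sensor.
tiny_env <- function(seed = 1, n_sensors = 1, reward_mode = "redistributed") {
  f <- matrix(c(5, 0, 1, 0), 2, 2)  # pressure at (0,0) and (1,0)
  v <- pressure_video(array(f, dim = c(2, 2, 1)))
  placement_env(v, n_sensors = n_sensors, reward_mode = reward_mode,
                seed = seed)
}
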