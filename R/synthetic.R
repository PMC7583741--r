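#' Generate the structured testing video
#'
#' A deterministic pressure video for validating the placement environment:
#' the first and last frames carry no pressure, and in between each support
#' cell's magnitude ramps up and back down (triangular in time, with the
#' ramps phase-shifted along the support path so the COP travels). Because
#' the nonzero support spans at most `n_sensors` cells, a placement covering
#' the full support reproduces the COP trajectory exactly and attains the
#' environment's maximum episodic reward of 1.
#'
#' @param grid `c(H, W)` dimensions (default `c(20, 7)`).
#' @param support n x 2 matrix of 0-based `(y, x)` support cells (at most 8
#'   by default); `NULL` picks 8 cells staggered around the grid midline.
#' @param n_frames total frame count including the empty first and last
#'   frames (default 12).
#' @param peak peak cell pressure in kPa (default 100).
#' @param ramp_width half-width of each cell's triangular ramp on the
#'   normalized time axis (default 0.6; larger values overlap more cells
#'   per frame).
#' @param frame_rate frames per second.
#' @return a `pressure_video`.
#' @examples
#' v <- make_testing_video()
#' frame_totals(v)[c(1, 12)]  # empty first and last frames
#' @export
make_testing_video <- function(grid = c(20, 7), support = NULL, n_frames = 12,
                               peak = 100, ramp_width = 0.6,
                               frame_rate = 100) {
  h <- grid[1]; w <- grid[2]
  if (is.null(support)) {
    mid <- (w - 1) %/% 2
    ys <- round(seq(2, h - 3, length.out = 8))
    xs <- rep(c(mid - 1, mid + 1, mid, mid - 1, mid + 1, mid, mid - 1, mid + 1),
              length.out = 8)
    support <- cbind(y = ys, x = xs)
  }
  support <- as.matrix(support)
  stopifnot(ncol(support) == 2, n_frames >= 3, peak > 0)
  if (anyDuplicated(paste(support[, 1], support[, 2]))) {
    stop("support cells must be distinct")
  }
  if (any(support[, 1] < 0 | support[, 1] >= h |
          support[, 2] < 0 | support[, 2] >= w)) {
    stop("support cell out of grid range")
  }
  k <- nrow(support)
  active <- 2:(n_frames - 1)
  u <- if (length(active) == 1) 0.5 else seq(0, 1, length.out = length(active))
  centers <- if (k == 1) 0.5 else seq(0, 1, length.out = k)
  frames <- array(0, dim = c(h, w, n_frames))
  for (j in seq_along(active)) {
    mag <- peak * pmax(0, 1 - abs(u[j] - centers) / ramp_width)
    for (c in seq_len(k)) {
      frames[support[c, 1] + 1, support[c, 2] + 1, active[j]] <- mag[c]
    }
  }
  pressure_video(frames, frame_rate = frame_rate)
}

#' Generate a synthetic stance-phase running video
#'
#' Emulates one stance phase of running on the working grid: a 2D Gaussian
#' pressure blob translates from heel to toe while the total force follows
#' a double-hump (impact peak, push-off peak) profile, with optional
#' multiplicative noise. Deterministic given the seed.
#'
#' @param grid `c(H, W)` dimensions (default `c(20, 7)`).
#' @param n_frames stance frames (default 30; 0.3 s at 100 Hz).
#' @param heel,toe blob-center start and end as `(y, x)` in 0-based cell
#'   units.
#' @param sigma blob standard deviation in cells.
#' @param peaks heights of the two force humps (kPa-cells).
#' @param noise_sd multiplicative noise standard deviation (0 disables).
#' @param frame_rate frames per second.
#' @param seed integer seed.
#' @return a `stance_video` (every frame carries load).
#' @export
make_gait_video <- function(grid = c(20, 7), n_frames = 30,
                            heel = c(3, 3.5), toe = c(16.5, 2.5),
                            sigma = 1.8, peaks = c(900, 1100),
                            noise_sd = 0.05, frame_rate = 100, seed = 1) {
  h <- grid[1]; w <- grid[2]
  stopifnot(n_frames >= 2)
  rng <- rng_stream(seed)
  u <- seq(0, 1, length.out = n_frames)
  # slow COP progression during mid-stance, faster at touch-down/push-off
  s <- u + 0.15 * sin(2 * pi * u)
  s <- (s - min(s)) / (max(s) - min(s))
  cy <- heel[1] + s * (toe[1] - heel[1])
  cx <- heel[2] + s * (toe[2] - heel[2])
  force <- peaks[1] * exp(-((u - 0.25) / 0.16)^2) +
    peaks[2] * exp(-((u - 0.7) / 0.2)^2)
  ys <- matrix(0:(h - 1), h, w)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  frames <- array(0, dim = c(h, w, n_frames))
  for (t in seq_len(n_frames)) {
    kern <- exp(-((ys - cy[t])^2 + (xs - cx[t])^2) / (2 * sigma^2))
    f <- force[t] * kern / sum(kern)
    if (noise_sd > 0) {
      f <- pmax(f * (1 + noise_sd * rng_rnorm(rng, h * w)), 0)
    }
    frames[, , t] <- f
  }
  v <- pressure_video(frames, frame_rate = frame_rate)
  segs <- split_stance_phases(v)
  if (length(segs) != 1) stop("generator produced a non-contiguous stance")
  segs[[1]]
}

#' A seeded dataset of synthetic stance videos
#'
#' Draws per-video geometry (heel/toe positions, blob width, force peaks)
#' from modest ranges around the defaults of [make_gait_video()], emulating
#' between-stride and between-subject variation.
#'
#' @param n number of videos.
#' @param seed integer seed.
#' @param grid `c(H, W)` dimensions.
#' @return a list of `stance_video` objects.
#' @export
make_gait_dataset <- function(n, seed = 1, grid = c(20, 7)) {
  rng <- rng_stream(seed)
  lapply(seq_len(n), function(i) {
    make_gait_video(
      grid = grid,
      n_frames = 24 + rng_sample_int(rng, 12, 1),
      heel = c(rng_runif(rng, 1, 2.0, 4.0), rng_runif(rng, 1, 2.8, 4.2)),
      toe = c(rng_runif(rng, 1, 15.0, 17.5), rng_runif(rng, 1, 1.8, 3.2)),
      sigma = rng_runif(rng, 1, 1.4, 2.2),
      peaks = c(rng_runif(rng, 1, 700, 1100), rng_runif(rng, 1, 900, 1300)),
      noise_sd = 0.05,
      seed = rng_spawn_seed(rng)
    )
  })
}

#' Brute-force optimal placement
#'
#' Exhaustively evaluates the episode reward of every `n_sensors`-subset of
#' grid cells. Because the reward masks by the support of the counts,
#' duplicate sensors never help, so subset enumeration covers the full
#' multiset search space. Feasible only on small instances; the search the
#' agent performs on the working grid spans 140^8 > 1.16e17 ordered
#' placements.
#'
#' @param video a `pressure_video`.
#' @param n_sensors sensors to place.
#' @param params a [reward_params()].
#' @param cap refuse instances whose multiset count
#'   `choose(H*W + n_sensors - 1, n_sensors)` exceeds this (default 1e6).
#' @return `list(placements, value)`: all optimal placements (ties, in
#'   lexicographic order of their sorted 0-based cell indices) and the
#'   optimal reward.
#' @export
brute_force_optimal <- function(video, n_sensors, params = reward_params(),
                                cap = 1e6) {
  d <- grid_dim(video)
  n_cells <- prod(d)
  if (choose(n_cells + n_sensors - 1, n_sensors) > cap) {
    stop(sprintf(
      "search space %.3g exceeds cap %.3g; use a smaller grid or fewer sensors",
      choose(n_cells + n_sensors - 1, n_sensors), cap))
  }
  k <- min(n_sensors, n_cells)
  pc <- video_precomp(video)
  subsets <- utils::combn(n_cells, k)
  vals <- apply(subsets, 2, function(cells1) {
    m <- masked_moments(pc, cells1)
    reward_from_moments(pc, m$tot, m$sx, m$sy, params)
  })
  best <- max(vals)
  ties <- which(vals >= best - 1e-12)
  placements <- lapply(ties, function(i) {
    placement(subsets[, i] - 1L, grid = d, n_sensors = n_sensors)
  })
  list(placements = placements, value = best)
}

#' Mean episode reward of a placement over a video set
#'
#' With `episodes = NULL` the mean is over the given videos; otherwise
#' `episodes` videos are drawn uniformly with replacement (seeded), the
#' protocol used for final placement comparisons.
#'
#' @param placement a [placement()] (e.g. a learned layout or a fixed
#'   reference layout loaded with [read_placement()]).
#' @param videos a list of `pressure_video` objects.
#' @param params a [reward_params()].
#' @param episodes optional number of sampled episodes.
#' @param seed seed for the episode draws.
#' @return the mean reward, a scalar.
#' @export
evaluate_placement <- function(placement, videos, params = reward_params(),
                               episodes = NULL, seed = 1) {
  if (inherits(videos, "pressure_video")) videos <- list(videos)
  if (length(videos) == 0) stop("empty video set")
  per_video <- vapply(videos, function(v) {
    episode_reward(v, placement, params)
  }, numeric(1))
  if (is.null(episodes)) return(mean(per_video))
  rng <- rng_stream(seed)
  idx <- rng_sample_int(rng, length(videos), episodes, replace = TRUE)
  mean(per_video[idx])
}
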