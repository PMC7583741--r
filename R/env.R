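#' The sensor-placement environment
#'
#' A discrete-action MDP: an episode starts from an empty H x W board and a
#' pressure video drawn uniformly from the dataset; at each step the agent
#' places one sensor on a cell (repeats allowed); the episode ends after
#' exactly `n_sensors` steps. In `"terminal"` reward mode all rewards are 0
#' except the last, which is the episode reward of the final placement. In
#' `"redistributed"` mode (the default) each step earns the marginal change
#' in accumulative reward (see [redistribute_rewards()]); the per-step
#' rewards telescope to the same terminal value.
#'
#' The state observed by the agent is the H x W sensor-count grid; the
#' number of sensors remaining is implied by its sum.
#'
#' @param videos a `pressure_video` or list of them, all on the same grid.
#' @param n_sensors sensors per episode (default 8).
#' @param reward_mode `"redistributed"` or `"terminal"`.
#' @param params a [reward_params()] object.
#' @param seed integer seed for the episode video draws.
#' @return an object of class `placement_env` (mutable).
#' @examples
#' env <- placement_env(make_testing_video(), seed = 1)
#' s <- env_reset(env)
#' out <- env_step(env, 0L)   # place a sensor on cell (y = 0, x = 0)
#' @export
placement_env <- function(videos, n_sensors = 8,
                          reward_mode = c("redistributed", "terminal"),
                          params = reward_params(), seed = 1) {
  if (inherits(videos, "pressure_video")) videos <- list(videos)
  if (length(videos) == 0) stop("empty video dataset")
  reward_mode <- match.arg(reward_mode)
  grid <- grid_dim(videos[[1]])
  for (v in videos) {
    if (!identical(grid_dim(v), grid)) stop("videos must share one grid")
  }
  e <- new.env(parent = emptyenv())
  e$grid <- grid
  e$n_actions <- prod(grid)
  e$n_sensors <- as.integer(n_sensors)
  e$reward_mode <- reward_mode
  e$params <- params
  e$precomp <- lapply(videos, video_precomp)
  e$rng <- rng_stream(seed)
  e$started <- FALSE
  e$done <- TRUE
  e$ep_n <- 0L
  e$video_log_buf <- integer(1024)
  class(e) <- "placement_env"
  e
}

#' @export
print.placement_env <- function(x, ...) {
  cat(sprintf("<placement_env> %d x %d board, %d sensors, %d video%s, %s rewards\n",
              x$grid[1], x$grid[2], x$n_sensors, length(x$precomp),
              if (length(x$precomp) == 1) "" else "s", x$reward_mode))
  invisible(x)
}

#' @rdname placement_env
#' @param env a `placement_env`.
#' @return `env_reset()` returns the initial state: an all-zero H x W
#'   integer count matrix.
#' @export
env_reset <- function(env) {
  env$video_idx <- rng_sample_int(env$rng, length(env$precomp), 1)
  env$pc <- env$precomp[[env$video_idx]]
  if (env$ep_n == length(env$video_log_buf)) {
    env$video_log_buf <- c(env$video_log_buf, integer(env$ep_n))
  }
  env$ep_n <- env$ep_n + 1L
  env$video_log_buf[env$ep_n] <- env$video_idx
  env$counts <- matrix(0L, env$grid[1], env$grid[2])
  env$covered <- logical(env$n_actions)
  nfr <- length(env$pc$tot)
  env$m_tot <- numeric(nfr); env$m_sx <- numeric(nfr); env$m_sy <- numeric(nfr)
  env$sensors_remaining <- env$n_sensors
  env$acc_reward <- 0     # A_0: empty placement scores 0
  env$done <- FALSE
  env$started <- TRUE
  env$counts
}

#' @rdname placement_env
#' @param action 0-based row-major cell index in `[0, H*W)`.
#' @return `env_step()` returns `list(state, reward, done)`.
#' @export
env_step <- function(env, action) {
  if (!env$started || env$done) stop("episode is done; call env_reset()")
  action <- as.integer(action)
  if (action < 0 || action >= env$n_actions) {
    stop(sprintf("action %d out of range [0, %d)", action, env$n_actions))
  }
  w <- env$grid[2]
  env$counts[action %/% w + 1L, action %% w + 1L] <-
    env$counts[action %/% w + 1L, action %% w + 1L] + 1L
  c1 <- action + 1L
  if (!env$covered[c1]) {
    env$covered[c1] <- TRUE
    row <- env$pc$p[c1, ]
    env$m_tot <- env$m_tot + row
    env$m_sx <- env$m_sx + row * env$pc$xs[c1]
    env$m_sy <- env$m_sy + row * env$pc$ys[c1]
  }
  env$sensors_remaining <- env$sensors_remaining - 1L
  env$done <- env$sensors_remaining == 0L
  a_t <- reward_from_moments(env$pc, env$m_tot, env$m_sx, env$m_sy, env$params)
  reward <- if (env$reward_mode == "redistributed") {
    r <- a_t - env$acc_reward
    env$acc_reward <- a_t
    r
  } else {
    if (env$done) a_t else 0
  }
  if (env$done) env$final_reward <- a_t
  list(state = env$counts, reward = reward, done = env$done)
}

#' @rdname placement_env
#' @return `env_placement()` returns the current board as a [placement()].
#' @export
env_placement <- function(env) {
  placement(counts = env$counts, grid = env$grid, n_sensors = env$n_sensors)
}

#' @rdname placement_env
#' @return `env_video_log()` returns the 1-based index of the video used by
#'   each episode so far, for reproducibility audits.
#' @export
env_video_log <- function(env) {
  env$video_log_buf[seq_len(env$ep_n)]
}
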