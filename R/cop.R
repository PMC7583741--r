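#' Center-of-pressure trajectory of a video
#'
#' The COP of a frame is the pressure-weighted mean of the 0-based cell
#' coordinates: `x = sum(p * coord_x) / sum(p)` and likewise for `y`.
#' Frames with zero total pressure have no COP and are flagged undefined.
#'
#' @param video a `pressure_video`.
#' @return a tibble with one row per frame: `frame` (1-based), `x`
#'   (mediolateral, cell units), `y` (anteroposterior, cell units) and
#'   `defined`. Class `cop_trajectory` for plotting.
#' @examples
#' v <- pressure_video(array(1, dim = c(20, 7, 1)))
#' cop_trajectory(v)  # centroid of a uniform field: (3, 9.5)
#' @export
cop_trajectory <- function(video) {
  pc <- video_precomp(video)
  out <- tibble::tibble(frame = seq_len(length(pc$tot)),
                        x = pc$cop_x, y = pc$cop_y, defined = pc$defined)
  class(out) <- c("cop_trajectory", class(out))
  out
}

#' Reward parameters
#'
#' `maxdistance` is the grid diagonal `sqrt(W^2 + H^2)` in cell units -- the
#' normalizer that maps COP distances into `[0, 1]`. The exponent 0.4
#' sharpens the reward near zero distance so small improvements in fit
#' remain visible to the agent.
#'
#' @param exponent reward exponent (> 0), default 0.4.
#' @param maxdistance normalizing distance (> 0); default `NULL` derives
#'   `sqrt(W^2 + H^2)` from the video at evaluation time.
#' @export
reward_params <- function(exponent = 0.4, maxdistance = NULL) {
  stopifnot(exponent > 0, is.null(maxdistance) || maxdistance > 0)
  structure(list(exponent = exponent, maxdistance = maxdistance),
            class = "reward_params")
}

resolve_maxdistance <- function(params, grid) {
  if (!is.null(params$maxdistance)) return(params$maxdistance)
  sqrt(grid[1]^2 + grid[2]^2)
}

# Per-video quantities reused across many reward evaluations: the cell x
# frame pressure matrix in row-major cell order (matching action indices),
# per-cell coordinates, and the unmasked COP.
video_precomp <- function(video) {
  d <- dim(video$frames)
  h <- d[1]; w <- d[2]; nf <- d[3]
  p <- matrix(aperm(video$frames, c(2, 1, 3)), nrow = h * w, ncol = nf)
  xs <- rep(0:(w - 1), times = h)   # row-major: cell i -> (y = i %/% w, x = i %% w)
  ys <- rep(0:(h - 1), each = w)
  tot <- colSums(p)
  defined <- tot > 0
  cop_x <- ifelse(defined, colSums(p * xs) / tot, NA_real_)
  cop_y <- ifelse(defined, colSums(p * ys) / tot, NA_real_)
  list(grid = c(h, w), p = p, xs = xs, ys = ys, tot = tot,
       sx = colSums(p * xs), sy = colSums(p * ys),
       defined = defined, cop_x = cop_x, cop_y = cop_y)
}

# Reward from precomputed video stats and masked per-frame pressure moments.
# Frames whose unmasked COP is undefined are excluded; frames whose masked
# COP alone is undefined incur the maximal distance.
reward_from_moments <- function(pc, m_tot, m_sx, m_sy, params) {
  keep <- pc$defined
  if (!any(keep)) stop("no defined COP frames")
  maxd <- resolve_maxdistance(params, pc$grid)
  mt <- m_tot[keep]
  d <- rep(maxd, sum(keep))
  ok <- mt > 0
  if (any(ok)) {
    dx <- m_sx[keep][ok] / mt[ok] - pc$cop_x[keep][ok]
    dy <- m_sy[keep][ok] / mt[ok] - pc$cop_y[keep][ok]
    d[ok] <- pmin(sqrt(dx * dx + dy * dy), maxd)
  }
  (1 - mean(d) / maxd)^params$exponent
}

masked_moments <- function(pc, cells1) {
  if (length(cells1) == 0) {
    z <- numeric(length(pc$tot))
    return(list(tot = z, sx = z, sy = z))
  }
  pm <- pc$p[cells1, , drop = FALSE]
  list(tot = colSums(pm),
       sx = colSums(pm * pc$xs[cells1]),
       sy = colSums(pm * pc$ys[cells1]))
}

#' Mask a video with a sensor placement
#'
#' Pressure is kept at cells carrying at least one sensor and zeroed
#' elsewhere; extra sensors on an already covered cell have no effect.
#'
#' @param video a `pressure_video`.
#' @param placement a `placement` on the same grid.
#' @return the masked `pressure_video`.
#' @export
apply_mask <- function(video, placement) {
  d <- dim(video$frames)
  if (!identical(d[1:2], dim(placement$counts))) {
    stop(sprintf("grid mismatch: video %dx%d vs placement %dx%d",
                 d[1], d[2], nrow(placement$counts), ncol(placement$counts)))
  }
  mask <- placement$counts > 0
  out <- video
  out$frames <- video$frames * array(mask, dim = d)
  cls <- class(out)
  class(out) <- cls[cls != "stance_video"]  # masking can empty frames
  out
}

#' Episode reward of a placement on a video
#'
#' For each frame, `d_n` is the Euclidean distance between the COP of the
#' full video and the COP of the masked video. Frames whose full-video COP
#' is undefined (zero total pressure) are skipped; frames where only the
#' masked COP is undefined are charged the maximal distance. The reward is
#'
#'   `(1 - mean(d_n) / maxdistance) ^ exponent`
#'
#' and lies in `[0, 1]`, reaching 1 exactly when the masked trajectory
#' matches the full trajectory on every retained frame.
#'
#' @inheritParams apply_mask
#' @param params a [reward_params()] object.
#' @return a scalar reward in `[0, 1]`.
#' @examples
#' v <- pressure_video(array(1, dim = c(20, 7, 3)))
#' episode_reward(v, placement(counts = matrix(1, 20, 7), n_sensors = 140))
#' @export
episode_reward <- function(video, placement, params = reward_params()) {
  d <- dim(video$frames)
  if (!identical(d[1:2], dim(placement$counts))) stop("grid mismatch")
  pc <- video_precomp(video)
  cells1 <- which(t(placement$counts) > 0)  # row-major flat order, 1-based
  m <- masked_moments(pc, cells1)
  reward_from_moments(pc, m$tot, m$sx, m$sy, params)
}

#' Redistribute the terminal reward over placement steps
#'
#' The terminal episode reward is decomposed into per-step rewards by
#' differencing accumulative rewards of placement prefixes: `A_t` is the
#' episode reward of the placement formed by the first `t` actions (with
#' `A_0 = 0` for the empty placement) and `r_t = A_t - A_{t-1}`. The
#' telescoping sum makes `sum(r_t)` equal the terminal reward exactly. A
#' step that lands on an already covered cell earns 0, and a step that
#' worsens the masked COP fit earns a negative reward.
#'
#' @param video a `pressure_video`.
#' @param actions integer vector of 0-based row-major cell indices, one per
#'   sensor, in placement order.
#' @param params a [reward_params()] object.
#' @return numeric vector of per-step rewards, same length as `actions`.
#' @export
redistribute_rewards <- function(video, actions, params = reward_params()) {
  pc <- video_precomp(video)
  h <- pc$grid[1]; w <- pc$grid[2]
  actions <- as.integer(actions)
  if (any(actions < 0 | actions >= h * w)) stop("action out of range")
  nfr <- length(pc$tot)
  m_tot <- numeric(nfr); m_sx <- numeric(nfr); m_sy <- numeric(nfr)
  covered <- logical(h * w)
  a_prev <- 0
  out <- numeric(length(actions))
  for (t in seq_along(actions)) {
    c1 <- actions[t] + 1L
    if (!covered[c1]) {
      covered[c1] <- TRUE
      row <- pc$p[c1, ]
      m_tot <- m_tot + row
      m_sx <- m_sx + row * pc$xs[c1]
      m_sy <- m_sy + row * pc$ys[c1]
    }
    a_t <- reward_from_moments(pc, m_tot, m_sx, m_sy, params)
    out[t] <- a_t - a_prev
    a_prev <- a_t
  }
  out
}
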