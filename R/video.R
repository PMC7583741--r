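#' Plantar pressure videos
#'
#' A pressure video is an ordered sequence of H x W grids of non-negative
#' pressures (kPa) recorded at a fixed frame rate. Rows run along the foot's
#' long (anteroposterior) axis, columns along the mediolateral axis; the
#' working resolution after preprocessing is 20 x 7. `cell_area` carries the
#' per-cell area in arbitrary consistent units so that force = pressure x
#' area is well defined across resolutions.
#'
#' @param frames a numeric H x W x N array, or a list of H x W matrices.
#' @param frame_rate frames per second; must be positive.
#' @param cell_area area of one grid cell (arbitrary consistent units).
#' @return an object of class `pressure_video`.
#' @examples
#' v <- pressure_video(array(1, dim = c(4, 3, 2)))
#' n_frames(v)
#' @export
pressure_video <- function(frames, frame_rate = 100, cell_area = 1) {
  if (is.list(frames)) {
    if (length(frames) == 0) stop("no frames")
    dims <- dim(frames[[1]])
    if (is.null(dims) || length(dims) != 2) stop("frames must be matrices")
    for (i in seq_along(frames)) {
      if (!identical(dim(frames[[i]]), dims)) {
        stop(sprintf("frame %d has shape %s, expected %s", i,
                     paste(dim(frames[[i]]), collapse = "x"),
                     paste(dims, collapse = "x")))
      }
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims, length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("frames must be an H x W x N array or a list of matrices")
  }
  if (dim(frames)[3] == 0) stop("no frames")
  storage.mode(frames) <- "double"
  if (anyNA(frames) || any(!is.finite(frames))) stop("non-finite pressure value")
  if (any(frames < 0)) {
    bad <- which(apply(frames, 3, function(f) any(f < 0)))[1]
    stop(sprintf("negative pressure in frame %d", bad))
  }
  stopifnot(frame_rate > 0, cell_area > 0)
  structure(
    list(frames = frames, frame_rate = frame_rate, cell_area = cell_area),
    class = "pressure_video"
  )
}

#' @rdname pressure_video
#' @param video a `pressure_video`.
#' @export
n_frames <- function(video) dim(video$frames)[3]

#' @rdname pressure_video
#' @export
grid_dim <- function(video) dim(video$frames)[1:2]

#' @export
print.pressure_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<%s> %d x %d grid, %d frame%s @ %g Hz, cell area %g\n",
              class(x)[1], d[1], d[2], d[3], if (d[3] == 1) "" else "s",
              x$frame_rate, x$cell_area))
  invisible(x)
}

# A stance video is a pressure video in which every frame carries load.
new_stance_video <- function(video, segment = NA_integer_) {
  tot <- frame_totals(video)
  if (any(tot <= 0)) stop("stance video contains a zero-pressure frame")
  video$segment <- as.integer(segment)
  class(video) <- c("stance_video", "pressure_video")
  video
}

#' Per-frame total pressure
#' @param video a `pressure_video`.
#' @return numeric vector of length `n_frames(video)`.
#' @export
frame_totals <- function(video) {
  apply(video$frames, 3, sum)
}

#' Split a recording into stance-phase videos
#'
#' During the swing phase no cell carries load, so frames with zero total
#' pressure delimit ground-contact episodes. Each maximal run of loaded
#' frames becomes one stance video, in temporal order.
#'
#' @param video a `pressure_video`.
#' @param epsilon frame-total threshold below or at which a frame counts as
#'   unloaded. The default 0 treats any pressure as contact.
#' @return a list of `stance_video` objects (empty for an all-zero video).
#' @export
split_stance_phases <- function(video, epsilon = 0) {
  loaded <- frame_totals(video) > epsilon
  if (!any(loaded)) return(list())
  r <- rle(loaded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    idx <- starts[keep[i]]:ends[keep[i]]
    seg <- pressure_video(video$frames[, , idx, drop = FALSE],
                          frame_rate = video$frame_rate,
                          cell_area = video$cell_area)
    out[[i]] <- new_stance_video(seg, segment = i)
  }
  out
}

#' Select one representative stance video per temporal group
#'
#' Partitions the stance videos into `n_groups` contiguous-in-time groups of
#' (near-)equal size -- any remainder is absorbed by the earliest groups --
#' and draws one video uniformly from each group.
#'
#' @param segments list of stance videos in temporal order.
#' @param n_groups number of groups (default 5).
#' @param seed integer seed making the draw reproducible.
#' @return a list of `n_groups` stance videos.
#' @export
select_representatives <- function(segments, n_groups = 5, seed) {
  n <- length(segments)
  if (n < n_groups) {
    stop(sprintf("need at least %d stance videos, got %d", n_groups, n))
  }
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  picks <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_groups), function(g) {
      as.integer(starts[g]) + sample.int(sizes[g], 1) - 1L
    }, integer(1))
  })
  segments[picks]
}

#' Crop the unloaded border of a video
#'
#' Removes leading and trailing rows and columns that receive no pressure in
#' any frame. Interior unloaded rows/columns are kept: the output is the
#' bounding box of the union of loaded cells across frames.
#'
#' @param video a `pressure_video` with at least one loaded cell.
#' @return the cropped video.
#' @export
crop_white_border <- function(video) {
  any_load <- apply(video$frames > 0, c(1, 2), any)
  if (!any(any_load)) stop("nothing to crop: video has no pressure anywhere")
  rows <- range(which(apply(any_load, 1, any)))
  cols <- range(which(apply(any_load, 2, any)))
  out <- video
  out$frames <- video$frames[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  out
}

#' Downsample a video to a target grid, conserving force
#'
#' Converts each frame by the pressure relation P = F / A: every source cell
#' contributes force = pressure x area, the source grid is scaled uniformly
#' onto the target grid, force is distributed to target bins proportionally
#' to geometric overlap, and target pressure is accumulated force divided by
#' the target bin area. Total force per frame is conserved exactly up to
#' floating-point rounding, for any (including non-integer) resizing ratio.
#'
#' @param video a `pressure_video`.
#' @param target integer vector `c(H_t, W_t)`; default `c(20, 7)`, the
#'   working resolution (anteroposterior x mediolateral).
#' @return a `pressure_video` with `target` grid and rescaled `cell_area`.
#' @export
downsample_video <- function(video, target = c(20, 7)) {
  stopifnot(length(target) == 2, all(target >= 1))
  target <- as.integer(target)
  d <- dim(video$frames)
  hs <- d[1]; ws <- d[2]; nf <- d[3]
  ht <- target[1]; wt <- target[2]

  # overlap_frac[i, j]: fraction of source cell j (in normalized extent
  # coordinates) covered by target cell i along one axis; columns sum to 1.
  overlap_frac <- function(n_src, n_tgt) {
    sb <- seq(0, 1, length.out = n_src + 1)
    tb <- seq(0, 1, length.out = n_tgt + 1)
    lo <- outer(tb[-length(tb)], sb[-length(sb)], pmax)
    hi <- outer(tb[-1], sb[-1], pmin)
    pmax(hi - lo, 0) * n_src
  }
  oy <- overlap_frac(hs, ht)
  ox <- overlap_frac(ws, wt)

  area_src <- video$cell_area
  area_tgt <- area_src * (hs * ws) / (ht * wt)
  out <- array(0, dim = c(ht, wt, nf))
  for (k in seq_len(nf)) {
    force <- video$frames[, , k] * area_src
    out[, , k] <- (oy %*% force %*% t(ox)) / area_tgt
  }
  pressure_video(out, frame_rate = video$frame_rate, cell_area = area_tgt)
}

#' Full preprocessing pipeline for one recording
#'
#' Applies, in order: stance-phase splitting, temporal-group representative
#' selection, per-segment border cropping, and force-conserving downsampling
#' to the working grid.
#'
#' @inheritParams split_stance_phases
#' @inheritParams select_representatives
#' @inheritParams downsample_video
#' @return a list of `n_groups` stance videos on the `target` grid.
#' @export
preprocess_video <- function(video, n_groups = 5, target = c(20, 7),
                             seed, epsilon = 0) {
  segs <- split_stance_phases(video, epsilon = epsilon)
  reps <- select_representatives(segs, n_groups = n_groups, seed = seed)
  lapply(reps, function(s) {
    v <- downsample_video(crop_white_border(s), target = target)
    new_stance_video(v, segment = s$segment)
  })
}
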