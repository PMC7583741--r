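#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a COP trajectory
#'
#' Defined COP points in placement order on the grid plane; the path shows
#' the anteroposterior progression.
#'
#' @param object a `cop_trajectory` from [cop_trajectory()].
#' @param ... unused.
#' @method autoplot cop_trajectory
#' @export
autoplot.cop_trajectory <- function(object, ...) {
  d <- object[object$defined, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$frame)) +
    ggplot2::geom_path(linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mediolateral, cells)",
                  y = "y (anteroposterior, cells)", colour = "frame") +
    ggplot2::theme_minimal()
}

#' Plot training curves of an episode log
#'
#' Moving-average episodic reward against episode, one line per member.
#'
#' @param object a `copsense_log` tibble ([training_log()] or the `log` of a
#'   [run_population()] result).
#' @param window moving-average window (default 1000).
#' @param ... unused.
#' @method autoplot copsense_log
#' @export
autoplot.copsense_log <- function(object, window = 1000, ...) {
  if (!"member" %in% names(object)) object$member <- 1L
  parts <- lapply(split(object, object$member), function(g) {
    g$reward_ma <- moving_average(g$reward, window)
    g
  })
  d <- do.call(rbind, parts)
  ggplot2::ggplot(d, ggplot2::aes(.data$episode, .data$reward_ma,
                                  colour = factor(.data$member))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "episode", y = sprintf("episodic reward (MA %d)", window),
                  colour = "member") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.copsense_log
#' @param object a `copsense_run` from [run_experiment()].
#' @method autoplot copsense_run
#' @export
autoplot.copsense_run <- function(object, window = NULL, ...) {
  if (is.null(object$run)) stop("empty run: nothing to plot")
  autoplot.copsense_log(object$run$log,
                        window = window %||% object$config$ma_window)
}

#' Temperature traces of a run
#'
#' Each member's entropy temperature over episodes, on a log axis;
#' population-based training changes it only at ready events.
#'
#' @param run a `copsense_run`.
#' @export
plot_alpha_trace <- function(run) {
  if (is.null(run$run)) stop("empty run: nothing to plot")
  d <- run$run$log
  ggplot2::ggplot(d, ggplot2::aes(.data$episode, .data$alpha,
                                  colour = factor(.data$member))) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "episode", y = "entropy temperature",
                  colour = "member") +
    ggplot2::theme_minimal()
}

#' Plot a sensor placement over a pressure background
#'
#' Sensor counts drawn on the accumulated (per-cell maximum over frames)
#' pressure image of a video, the standard way to present a final layout.
#'
#' @param object a [placement()].
#' @param video optional `pressure_video` for the background.
#' @param ... unused.
#' @method autoplot placement
#' @export
autoplot.placement <- function(object, video = NULL, ...) {
  h <- nrow(object$counts); w <- ncol(object$counts)
  cells <- which(object$counts > 0, arr.ind = TRUE)
  d <- tibble::tibble(y = cells[, 1] - 1, x = cells[, 2] - 1,
                      n = object$counts[cells])
  p <- ggplot2::ggplot()
  if (!is.null(video)) {
    acc <- apply(video$frames, c(1, 2), max)
    bg <- tibble::tibble(y = rep(0:(h - 1), w),
                         x = rep(0:(w - 1), each = h),
                         pressure = as.vector(acc))
    p <- p + ggplot2::geom_tile(data = bg,
                                ggplot2::aes(.data$x, .data$y,
                                             fill = .data$pressure)) +
      ggplot2::scale_fill_gradient(low = "white", high = "firebrick")
  }
  p + ggplot2::geom_point(data = d,
                          ggplot2::aes(.data$x, .data$y, size = .data$n),
                          shape = 21, colour = "black", fill = "gold") +
    ggplot2::scale_size_area(max_size = 5, breaks = unique(d$n)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mediolateral)", y = "y (anteroposterior)",
                  size = "sensors") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
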