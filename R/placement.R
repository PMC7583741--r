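#' Sensor placements
#'
#' A placement assigns up to `n_sensors` discrete sensors to cells of the
#' H x W grid, represented as a grid of non-negative sensor counts. Several
#' sensors may share a cell; for the COP reward the mask is the support of
#' the counts, so duplicates are inert.
#'
#' Cells are addressed 0-based as `(y, x)` with `y` the row
#' (anteroposterior) and `x` the column (mediolateral) index, or by the
#' row-major flat index `y * W + x` used as the environment's action code.
#'
#' @param cells sensor positions: an n x 2 matrix of 0-based `(y, x)` pairs,
#'   or an integer vector of 0-based row-major flat indices. Repeats allowed.
#' @param grid `c(H, W)` grid dimensions (default `c(20, 7)`).
#' @param n_sensors sensor budget (default 8); `sum(counts) <= n_sensors`.
#' @param counts alternatively, a full H x W count matrix.
#' @return an object of class `placement`.
#' @examples
#' p <- placement(c(10, 10, 25), grid = c(20, 7))
#' sum(p$counts)  # 3 sensors on 2 distinct cells
#' @export
placement <- function(cells = NULL, grid = c(20, 7), n_sensors = 8,
                      counts = NULL) {
  if (!is.null(counts)) grid <- dim(as.matrix(counts))
  h <- as.integer(grid[1]); w <- as.integer(grid[2])
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (any(counts < 0) || any(counts != round(counts))) {
      stop("counts must be non-negative integers")
    }
  } else {
    counts <- matrix(0L, h, w)
    if (!is.null(cells) && length(cells) > 0) {
      if (is.matrix(cells)) {
        stopifnot(ncol(cells) == 2)
        ys <- cells[, 1]; xs <- cells[, 2]
      } else {
        idx <- as.integer(cells)
        ys <- idx %/% w; xs <- idx %% w
      }
      if (any(ys < 0 | ys >= h | xs < 0 | xs >= w)) {
        stop("cell index out of grid range")
      }
      for (i in seq_along(ys)) {
        counts[ys[i] + 1, xs[i] + 1] <- counts[ys[i] + 1, xs[i] + 1] + 1L
      }
    }
  }
  if (sum(counts) > n_sensors) {
    stop(sprintf("placement uses %d sensors but the budget is %d",
                 sum(counts), n_sensors))
  }
  structure(list(counts = counts, n_sensors = as.integer(n_sensors)),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement> %d x %d grid, %d/%d sensors on %d cells\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$n_sensors,
              sum(x$counts > 0)))
  invisible(x)
}

#' @rdname placement
#' @param placement a `placement`.
#' @return `placement_cells()` returns the occupied cells as an n x 2 matrix
#'   of 0-based `(y, x)` pairs (one row per sensor, duplicates repeated).
#' @export
placement_cells <- function(placement) {
  idx <- which(placement$counts > 0, arr.ind = TRUE)
  reps <- placement$counts[placement$counts > 0]
  cbind(y = rep(idx[, 1] - 1L, reps), x = rep(idx[, 2] - 1L, reps))
}

#' Read / write placements as JSON
#'
#' Format: `{"grid": [H, W], "sensors": [[y, x], ...]}` with 0-based
#' indices, e.g. for exchanging fixed layouts with other tools.
#'
#' @param path JSON file path.
#' @inheritParams placement_cells
#' @param n_sensors sensor budget recorded on read (defaults to the number
#'   of sensors listed).
#' @export
read_placement <- function(path, n_sensors = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$grid) || length(obj$grid) != 2) stop("missing 'grid' [H, W]")
  sensors <- obj$sensors
  if (is.null(sensors) || length(sensors) == 0) {
    cells <- NULL
    k <- 0
  } else {
    cells <- matrix(as.integer(sensors), ncol = 2)
    k <- nrow(cells)
  }
  placement(cells, grid = as.integer(obj$grid),
            n_sensors = if (is.null(n_sensors)) max(k, 1) else n_sensors)
}

#' @rdname read_placement
#' @export
write_placement <- function(placement, path) {
  cells <- placement_cells(placement)
  obj <- list(grid = as.integer(dim(placement$counts)),
              sensors = unname(lapply(seq_len(nrow(cells)),
                                      function(i) as.integer(cells[i, ]))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}
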