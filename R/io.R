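#' Read and write pressure videos
#'
#' The native text format (".ppv") is a header line
#' `ppv <H> <W> <frame_rate_hz> [<cell_area>]` followed by the frames, each
#' as H whitespace-separated rows of W decimal values, frames separated by a
#' blank line. Values are written with 17 significant digits so a
#' write/read round trip is bitwise exact. `read_video()` also accepts a
#' directory of one-frame-per-file CSVs (no header), ordered by file name.
#'
#' @param path file (or, for reading, directory) path.
#' @param video a `pressure_video`.
#' @return `read_video()` returns a `pressure_video`; `write_video()`
#'   returns `path` invisibly.
#' @export
read_video <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) stop("no frames")
    frames <- lapply(files, function(f) {
      as.matrix(utils::read.csv(f, header = FALSE))
    })
    return(pressure_video(lapply(frames, unname)))
  }
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) stop("no frames")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) < 4 || header[1] != "ppv") {
    stop("malformed header: expected 'ppv <H> <W> <frame_rate_hz>'")
  }
  h <- as.integer(header[2]); w <- as.integer(header[3])
  rate <- as.numeric(header[4])
  area <- if (length(header) >= 5) as.numeric(header[5]) else 1
  body <- lines[-1]
  blank <- !nzchar(trimws(body))
  # split rows into frame blocks at blank lines
  blocks <- split(body[!blank], cumsum(blank)[!blank])
  if (length(blocks) == 0) stop("no frames")
  frames <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    rows <- blocks[[i]]
    if (length(rows) != h) {
      stop(sprintf("frame %d: expected %d rows, got %d", i, h, length(rows)))
    }
    vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    nc <- lengths(vals)
    if (any(nc != w)) {
      stop(sprintf("frame %d: ragged rows (expected %d values per row)", i, w))
    }
    m <- do.call(rbind, vals)
    if (anyNA(m)) stop(sprintf("frame %d: non-numeric value", i))
    if (any(m < 0)) stop(sprintf("frame %d: negative pressure", i))
    frames[[i]] <- m
  }
  pressure_video(frames, frame_rate = rate, cell_area = area)
}

#' @rdname read_video
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "pressure_video"))
  d <- dim(video$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ppv %d %d %s %s", d[1], d[2],
                     num17(video$frame_rate), num17(video$cell_area)), con)
  for (k in seq_len(d[3])) {
    f <- video$frames[, , k]
    writeLines(apply(f, 1, function(r) paste(num17(r), collapse = " ")), con)
    if (k < d[3]) writeLines("", con)
  }
  invisible(path)
}

# shortest decimal representation that round-trips a double exactly
num17 <- function(x) {
  vapply(x, function(v) {
    for (digits in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", digits, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}
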