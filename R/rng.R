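#' Independent seeded random-number streams
#'
#' Training interleaves several stochastic processes (episode video draws,
#' action sampling, replay sampling, population perturbations). Each gets its
#' own stream so that adding draws to one process never shifts another, and a
#' run is fully determined by its seed. Streams snapshot and restore R's
#' global RNG state around every draw, so they never perturb user code.
#'
#' @param seed integer seed for the stream.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  glob <- globalenv()
  old <- get0(".Random.seed", envir = glob, inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = glob)
  if (is.null(old)) {
    rm(".Random.seed", envir = glob)
  } else {
    assign(".Random.seed", old, envir = glob)
  }
  class(e) <- "rng_stream"
  e
}

# Evaluate fn() under the stream's RNG state, then save it back.
with_rng <- function(rng, fn) {
  stopifnot(inherits(rng, "rng_stream"))
  glob <- globalenv()
  old <- get0(".Random.seed", envir = glob, inherits = FALSE)
  assign(".Random.seed", rng$state, envir = glob)
  on.exit({
    rng$state <- get(".Random.seed", envir = glob)
    if (is.null(old)) {
      rm(".Random.seed", envir = glob)
    } else {
      assign(".Random.seed", old, envir = glob)
    }
  })
  fn()
}

rng_runif <- function(rng, n = 1, min = 0, max = 1) {
  with_rng(rng, function() stats::runif(n, min, max))
}

rng_rnorm <- function(rng, n = 1, mean = 0, sd = 1) {
  with_rng(rng, function() stats::rnorm(n, mean, sd))
}

# Uniform draw of `size` integers from 1..n.
rng_sample_int <- function(rng, n, size = 1, replace = FALSE, prob = NULL) {
  with_rng(rng, function() sample.int(n, size, replace = replace, prob = prob))
}

# Derive a child seed; children are independent of later parent draws.
rng_spawn_seed <- function(rng) {
  rng_sample_int(rng, .Machine$integer.max, 1)
}
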