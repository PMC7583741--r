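#' Configuration for population-based training of the temperature
#'
#' A population of SAC-Discrete agents trains in parallel (here: in
#' synchronous round-robin slices, which makes runs bit-reproducible on one
#' machine). Periodically each member is evaluated and, when ready, a
#' bottom-fraction member copies the parameters and temperature of a random
#' top-fraction member and perturbs the temperature.
#'
#' @param pop_size number of members (reference setting: 15).
#' @param exploit_frac fraction defining the top/bottom sets (0.2; the set
#'   size is `ceiling(exploit_frac * pop_size)`).
#' @param perturb_factors multiplicative temperature perturbations drawn
#'   uniformly after an exploit copy (0.8 or 1.2).
#' @param ready_interval agent steps a member must accumulate since it was
#'   last ready before the next exploit/explore pass (reference: 5e5).
#' @param alpha_init_range temperatures are initialized log-uniformly on
#'   this range (reference: `[1e-3, 1e-1]`).
#' @param eval_window episodes averaged by the performance measure (10).
#' @param slice_steps agent steps per member per round-robin slice.
#' @param seed master seed; member seeds are derived from it.
#' @export
pbt_config <- function(pop_size = 15, exploit_frac = 0.2,
                       perturb_factors = c(0.8, 1.2), ready_interval = 5e5,
                       alpha_init_range = c(1e-3, 1e-1), eval_window = 10,
                       slice_steps = 1e4, seed = 1) {
  stopifnot(pop_size >= 1, exploit_frac > 0, exploit_frac <= 0.5,
            all(perturb_factors > 0), ready_interval >= 1,
            length(alpha_init_range) == 2, all(alpha_init_range > 0),
            eval_window >= 1, slice_steps >= 1)
  structure(list(pop_size = as.integer(pop_size),
                 exploit_frac = exploit_frac,
                 perturb_factors = perturb_factors,
                 ready_interval = ready_interval,
                 alpha_init_range = sort(alpha_init_range),
                 eval_window = as.integer(eval_window),
                 slice_steps = as.integer(slice_steps),
                 seed = as.integer(seed)),
            class = "pbt_config")
}

#' Performance measure of a member
#'
#' The arithmetic mean of the last `window` episodic rewards (or of all
#' episodes when fewer have completed).
#'
#' @param rewards numeric vector of episodic rewards in temporal order.
#' @param window number of trailing episodes to average (default 10).
#' @return the mean, a scalar.
#' @export
eval_member <- function(rewards, window = 10) {
  n <- length(rewards)
  if (n == 0) stop("no completed episodes to evaluate")
  mean(rewards[(n - min(window, n) + 1):n])
}

#' Ready predicate
#'
#' A member is ready for the exploit/explore pass once it has accumulated
#' at least `ready_interval` agent steps since it was last ready; the
#' counter resets after the pass.
#'
#' @param steps_since_ready agent steps since the member was last ready.
#' @param ready_interval the threshold.
#' @export
pbt_ready <- function(steps_since_ready, ready_interval) {
  steps_since_ready >= ready_interval
}

# Rank indices by performance, best first; ties broken by member index
# (stable order).
rank_members <- function(perfs) {
  order(-perfs, seq_along(perfs))
}

#' Exploit decision for one member
#'
#' Members are ranked by performance (descending, stable in member index).
#' If `member` falls in the bottom `ceiling(frac * N)` it draws a source
#' uniformly from the top `ceiling(frac * N)` whose parameters and
#' temperature it will copy; otherwise it is left unchanged.
#'
#' @param perfs performance of every member (all must be evaluated).
#' @param member index of the member under consideration.
#' @param frac exploit fraction (default 0.2).
#' @param rng an [rng_stream()].
#' @return `list(copy, source)`: `copy` is TRUE when a copy should happen,
#'   `source` the member index to copy from (NA otherwise).
#' @export
pbt_exploit <- function(perfs, member, frac = 0.2, rng) {
  if (anyNA(perfs)) stop("all members must be evaluated before exploit")
  n <- length(perfs)
  k <- ceiling(frac * n)
  ranked <- rank_members(perfs)
  top <- ranked[seq_len(k)]
  bottom <- ranked[(n - k + 1):n]
  if (!(member %in% bottom) || member %in% top) {
    return(list(copy = FALSE, source = NA_integer_))
  }
  list(copy = TRUE, source = top[rng_sample_int(rng, k, 1)])
}

#' Explore: perturb the temperature after an exploit copy
#'
#' @param alpha current entropy temperature.
#' @param factors candidate multiplicative factors (default `c(0.8, 1.2)`).
#' @param rng an [rng_stream()].
#' @return the perturbed temperature.
#' @export
pbt_explore <- function(alpha, factors = c(0.8, 1.2), rng) {
  alpha * factors[rng_sample_int(rng, length(factors), 1)]
}

copy_member_networks <- function(dst, src) {
  dst$policy <- src$policy
  dst$q1 <- src$q1
  dst$q2 <- src$q2
  dst$q1_targ <- src$q1_targ
  dst$q2_targ <- src$q2_targ
  dst$opt_policy <- src$opt_policy
  dst$opt_q1 <- src$opt_q1
  dst$opt_q2 <- src$opt_q2
  invisible(dst)
}

#' Run population-based training
#'
#' Trains `pop_size` SAC-Discrete agents in synchronous round-robin slices
#' of `slice_steps` agent steps until the population has consumed
#' `total_steps` agent steps in total. After each slice the member is
#' evaluated (mean of its trailing `eval_window` episodic rewards) and,
#' when ready, undergoes the exploit/explore pass on its temperature.
#'
#' @param env_factory function `(seed) -> placement_env`; each member gets
#'   its own environment with a derived seed.
#' @param total_steps total agent steps across the whole population.
#' @param pbt a [pbt_config()].
#' @param sac a [sac_config()]; its `alpha` and `seed` are overridden per
#'   member (log-uniform initial temperatures, derived seeds).
#' @return an object of class `pbt_run`: a list with `best` (index of the
#'   best-performing member), `members` (the agents), `perfs`, and `log`
#'   (a per-member episode tibble, see [training_log()]).
#' @export
run_population <- function(env_factory, total_steps, pbt = pbt_config(),
                           sac = sac_config()) {
  rng <- rng_stream(pbt$seed)
  n <- pbt$pop_size
  lo <- log(pbt$alpha_init_range[1]); hi <- log(pbt$alpha_init_range[2])
  alphas0 <- exp(rng_runif(rng, n, lo, hi))
  members <- vector("list", n)
  envs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- sac
    cfg$alpha <- alphas0[i]
    cfg$seed <- rng_spawn_seed(rng)
    envs[[i]] <- env_factory(rng_spawn_seed(rng))
    members[[i]] <- sac_agent(envs[[i]]$grid, envs[[i]]$n_sensors, cfg)
  }
  perfs <- rep(NA_real_, n)
  since_ready <- numeric(n)
  done_steps <- 0
  while (done_steps < total_steps) {
    for (i in seq_len(n)) {
      if (done_steps >= total_steps) break
      slice <- min(pbt$slice_steps, total_steps - done_steps)
      sac_train(envs[[i]], slice, agent = members[[i]])
      done_steps <- done_steps + slice
      since_ready[i] <- since_ready[i] + slice
      if (members[[i]]$ep_n > 0) {
        perfs[i] <- eval_member(episode_rewards(members[[i]]), pbt$eval_window)
      }
      if (pbt_ready(since_ready[i], pbt$ready_interval) && !anyNA(perfs)) {
        dec <- pbt_exploit(perfs, i, pbt$exploit_frac, rng)
        if (dec$copy) {
          copy_member_networks(members[[i]], members[[dec$source]])
          members[[i]]$alpha <- pbt_explore(members[[dec$source]]$alpha,
                                            pbt$perturb_factors, rng)
        }
        since_ready[i] <- 0
      }
    }
  }
  logs <- lapply(seq_len(n), function(i) {
    lg <- training_log(members[[i]])
    lg$member <- i
    lg
  })
  log <- do.call(rbind, logs)
  class(log) <- c("copsense_log", class(tibble::tibble()))
  best <- if (anyNA(perfs)) NA_integer_ else rank_members(perfs)[1]
  structure(list(best = best, members = members, envs = envs,
                 perfs = perfs, log = log, pbt = pbt, sac = sac,
                 total_steps = done_steps),
            class = "pbt_run")
}

#' @export
print.pbt_run <- function(x, ...) {
  cat(sprintf("<pbt_run> %d members, %s agent steps, best member %s (p = %.4f)\n",
              length(x$members), format(x$total_steps, big.mark = ","),
              x$best, if (is.na(x$best)) NA else x$perfs[x$best]))
  invisible(x)
}
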