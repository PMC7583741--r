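#' Moving-average filter for reward curves
#'
#' Trailing average with edge handling by averaging over the available
#' history, so a constant series is mapped to itself from the first sample.
#'
#' @param x numeric series.
#' @param window window size (reference figures use 1000 episodes).
#' @return filtered series, same length as `x`.
#' @export
moving_average <- function(x, window = 1000) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0) return(numeric(0))
  cs <- cumsum(x)
  i <- seq_len(n)
  lag <- pmax(i - window, 0)
  (cs - c(0, cs)[lag + 1]) / (i - lag)
}

#' Experiment configuration
#'
#' Bundles everything that determines a run: the video source, environment
#' settings, SAC and PBT configurations, the agent-step budget and the
#' global seed. A run in the synchronous scheduler is fully determined by
#' its configuration.
#'
#' @param source `"testing"` (the structured testing video), `"gait"`
#'   (`n_videos` synthetic stance videos) or `"dir"` (a directory of `.ppv`
#'   files given by `data_dir`).
#' @param total_steps total agent steps across the population.
#' @param seed global seed; all member/environment/data seeds derive from it.
#' @param n_videos number of synthetic gait videos when `source = "gait"`.
#' @param data_dir directory of `.ppv` files when `source = "dir"`.
#' @param n_sensors sensors per episode.
#' @param reward_mode `"redistributed"` or `"terminal"`.
#' @param sac a [sac_config()].
#' @param pbt a [pbt_config()].
#' @param ma_window moving-average window for reported curves.
#' @param final_window episodes of the best member averaged for the summary
#'   (reference protocol: final 1000 episodes).
#' @export
run_config <- function(source = c("testing", "gait", "dir"),
                       total_steps = 2e5, seed = 1, n_videos = 20,
                       data_dir = NULL, n_sensors = 8,
                       reward_mode = "redistributed",
                       sac = sac_config(), pbt = pbt_config(),
                       ma_window = 1000, final_window = 1000) {
  source <- match.arg(source)
  if (source == "dir" && is.null(data_dir)) stop("source 'dir' needs data_dir")
  structure(list(source = source, total_steps = total_steps,
                 seed = as.integer(seed), n_videos = as.integer(n_videos),
                 data_dir = data_dir, n_sensors = as.integer(n_sensors),
                 reward_mode = reward_mode, sac = sac, pbt = pbt,
                 ma_window = as.integer(ma_window),
                 final_window = as.integer(final_window)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$sac <- unclass(obj$sac)
  obj$pbt <- unclass(obj$pbt)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sac <- do.call(sac_config, obj$sac)
  pbt <- do.call(pbt_config, obj$pbt)
  obj$sac <- NULL; obj$pbt <- NULL
  do.call(run_config, c(obj, list(sac = sac, pbt = pbt)))
}

#' Canonical scaled experiment configurations
#'
#' The reference protocol (population 15, 10M agent steps, ready interval
#' 5e5) is scaled to desk size with the same structure: population 3, 2e5
#' total agent steps, ready interval 1e4 member steps (the same ~5%
#' proportion of the per-member budget), round-robin slices of 2e3 steps.
#' `config_testing_experiment()` targets the structured testing video;
#' `config_gait_experiment()` targets a synthetic stance-video dataset.
#'
#' @param seed global seed.
#' @param total_steps total agent steps across the population.
#' @param pop_size population size.
#' @param n_videos gait dataset size (gait experiment only).
#' @return a [run_config()].
#' @export
config_testing_experiment <- function(seed = 1, total_steps = 2e5,
                                      pop_size = 3) {
  run_config(
    source = "testing", total_steps = total_steps, seed = seed,
    sac = sac_config(),
    pbt = pbt_config(pop_size = pop_size, ready_interval = 1e4,
                     slice_steps = 2e3, seed = seed)
  )
}

#' @rdname config_testing_experiment
#' @export
config_gait_experiment <- function(seed = 1, total_steps = 2e5,
                                   pop_size = 3, n_videos = 20) {
  cfg <- config_testing_experiment(seed, total_steps, pop_size)
  cfg$source <- "gait"
  cfg$n_videos <- as.integer(n_videos)
  # placements competitive with strong distributed layouts are not the
  # myopic greedy chain; raise the discount so credit crosses steps
  cfg$sac$gamma <- 0.99
  cfg
}

# Build the per-member environment factory for a config. Data seeds derive
# from the config seed so the dataset is shared across members while each
# member's episode draws differ.
config_env_factory <- function(config) {
  videos <- switch(config$source,
    testing = list(make_testing_video()),
    gait = make_gait_dataset(config$n_videos, seed = config$seed + 104729L),
    dir = {
      files <- sort(list.files(config$data_dir, pattern = "\\.ppv$",
                               full.names = TRUE))
      if (length(files) == 0) stop("no .ppv files in data_dir")
      lapply(files, read_video)
    })
  function(seed) {
    placement_env(videos, n_sensors = config$n_sensors,
                  reward_mode = config$reward_mode, seed = seed)
  }
}

#' Run a full experiment and write its artifacts
#'
#' Executes population-based training under `config` and writes to
#' `out_dir`: the configuration echo (`config.yaml`), the per-member
#' episode log (`log.jsonl`, one JSON record per episode), the
#' moving-average reward curve per member (`curves.csv`), the best member's
#' greedy placement (`placement.json`) and checkpoint (`checkpoint.rds`,
#' see [save_agent()]), a numeric summary (`summary.json`), and
#' reward/temperature curve plots (PNG) unless `plots = FALSE`. A zero-step budget writes the config echo and empty
#' logs only.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param plots write PNG figures (default TRUE).
#' @return an object of class `copsense_run` (invisibly): the [run_population()]
#'   result plus the config, summary and output directory.
#' @export
run_experiment <- function(config, out_dir, plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  if (config$total_steps <= 0) {
    file.create(file.path(out_dir, "log.jsonl"))
    res <- structure(list(run = NULL, config = config, summary = NULL,
                          dir = out_dir), class = "copsense_run")
    return(invisible(res))
  }
  pbt <- config$pbt
  pbt$seed <- config$seed
  run <- run_population(config_env_factory(config), config$total_steps,
                        pbt = pbt, sac = config$sac)
  lg <- run$log
  jsonl <- file(file.path(out_dir, "log.jsonl"), "w")
  writeLines(sprintf(
    '{"member": %d, "episode": %d, "reward": %.10g, "alpha": %.10g, "steps": %d}',
    lg$member, lg$episode, lg$reward, lg$alpha, lg$steps), jsonl)
  close(jsonl)
  curves <- do.call(rbind, lapply(split(lg, lg$member), function(g) {
    g$reward_ma <- moving_average(g$reward, config$ma_window)
    g
  }))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)

  best <- run$members[[run$best]]
  groll <- greedy_rollout(best, run$envs[[run$best]])
  write_placement(groll$placement, file.path(out_dir, "placement.json"))
  save_agent(best, file.path(out_dir, "checkpoint.rds"))
  rew <- episode_rewards(best)
  nf <- min(config$final_window, length(rew))
  summary <- list(
    best_member = run$best,
    best_perf = run$perfs[run$best],
    greedy_reward = groll$reward,
    final_mean_reward = mean(rew[(length(rew) - nf + 1):length(rew)]),
    final_window = nf,
    episodes = length(rew),
    total_steps = run$total_steps
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- structure(list(run = run, config = config, summary = summary,
                        greedy = groll, dir = out_dir),
                   class = "copsense_run")
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "reward_curve.png"),
                    ggplot2::autoplot(res), width = 7, height = 4, dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "alpha_trace.png"),
                    plot_alpha_trace(res), width = 7, height = 4, dpi = 120)
  }
  invisible(res)
}

#' @export
print.copsense_run <- function(x, ...) {
  if (is.null(x$run)) {
    cat("<copsense_run> empty run (zero-step budget)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<copsense_run> %s steps, best member %d: perf %.4f, greedy reward %.4f\n",
    format(x$summary$total_steps, big.mark = ","), x$summary$best_member,
    x$summary$best_perf, x$summary$greedy_reward))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-member summary of a run
#'
#' @param x a `copsense_run`.
#' @param ... unused.
#' @return one row per population member: episodes completed, final
#'   temperature, performance (trailing-window mean reward) and whether it
#'   is the selected best member.
#' @method tidy copsense_run
#' @export
tidy.copsense_run <- function(x, ...) {
  if (is.null(x$run)) return(tibble::tibble())
  run <- x$run
  tibble::tibble(
    member = seq_along(run$members),
    episodes = vapply(run$members, function(m) m$ep_n, integer(1)),
    alpha = vapply(run$members, function(m) m$alpha, numeric(1)),
    perf = run$perfs,
    best = seq_along(run$members) == run$best
  )
}

#' @rdname tidy.copsense_run
#' @method glance copsense_run
#' @export
glance.copsense_run <- function(x, ...) {
  if (is.null(x$run)) return(tibble::tibble())
  tibble::tibble(
    best_member = x$summary$best_member,
    best_perf = x$summary$best_perf,
    greedy_reward = x$summary$greedy_reward,
    final_mean_reward = x$summary$final_mean_reward,
    episodes = x$summary$episodes,
    total_steps = x$summary$total_steps
  )
}
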