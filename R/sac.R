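#' Configuration for the discrete Soft Actor-Critic agent
#'
#' The default discount is small (`gamma = 0.1`) because training uses
#' exactly redistributed rewards: each step's reward already carries that
#' action's full credit, so near-myopic values are unbiased while the
#' per-action advantage signal stays sharp. Raise `gamma` towards 1 when
#' training with `reward_mode = "terminal"`, where credit must propagate
#' backwards through the episode.
#'
#' @param gamma discount factor in `[0, 1]`.
#' @param tau Polyak coefficient in `[0, 1]`; targets update as
#'   `theta_bar <- tau * theta_bar + (1 - tau) * theta`, so large `tau`
#'   means slow target drift.
#' @param alpha entropy temperature (> 0) weighing policy entropy against
#'   reward. Fixed during training; population-based training perturbs it.
#' @param lr Adam learning rate (default 3e-4).
#' @param batch_size minibatch size for gradient steps.
#' @param update_every agent steps between gradient steps.
#' @param buffer_capacity replay-buffer capacity (FIFO).
#' @param warmup agent steps of uniform-random actions before any gradient
#'   step, to fill the buffer with diverse transitions.
#' @param hidden integer vector of hidden-layer widths for both the policy
#'   and the Q-networks.
#' @param seed integer seed for network initialization, action sampling and
#'   replay sampling.
#' @export
sac_config <- function(gamma = 0.1, tau = 0.995, alpha = 4e-3, lr = 3e-4,
                       batch_size = 64, update_every = 4,
                       buffer_capacity = 1e5, warmup = 1000,
                       hidden = c(128), seed = 1) {
  stopifnot(gamma >= 0, gamma <= 1, tau >= 0, tau <= 1, alpha > 0, lr > 0,
            batch_size >= 1, update_every >= 1, buffer_capacity >= 1,
            warmup >= 0, all(hidden >= 1))
  structure(list(gamma = gamma, tau = tau, alpha = alpha, lr = lr,
                 batch_size = as.integer(batch_size),
                 update_every = as.integer(update_every),
                 buffer_capacity = as.integer(buffer_capacity),
                 warmup = as.integer(warmup), hidden = as.integer(hidden),
                 seed = as.integer(seed)),
            class = "sac_config")
}

#' Replay buffer of environment transitions
#'
#' Fixed-capacity FIFO storage of `(s, a, r, s', done)` records with uniform
#' minibatch sampling (without replacement within a batch).
#'
#' @param capacity maximum number of stored transitions.
#' @param state_dim length of the flattened state vector.
#' @return a mutable object of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity, state_dim) {
  b <- new.env(parent = baseenv())   # evalq writes need base `{`, `[<-`
  b$capacity <- as.integer(capacity)
  b$s <- matrix(0, capacity, state_dim)
  b$s2 <- matrix(0, capacity, state_dim)
  b$a <- integer(capacity)
  b$r <- numeric(capacity)
  b$d <- numeric(capacity)
  b$size <- 0L
  b$ptr <- 0L
  class(b) <- "replay_buffer"
  b
}

#' @rdname replay_buffer
#' @param buffer a `replay_buffer`.
#' @param s,s2 flattened state / next-state vectors.
#' @param a 0-based action index.
#' @param r reward.
#' @param done logical episode-termination flag.
#' @export
buffer_add <- function(buffer, s, a, r, s2, done) {
  # write through the buffer's own frame: `buffer$s[i, ] <-` would duplicate
  # the full storage matrix on every insertion
  buffer$.in_s <- s
  buffer$.in_s2 <- s2
  buffer$.in_a <- as.integer(a)
  buffer$.in_r <- r
  buffer$.in_d <- as.numeric(done)
  evalq({
    ptr <- ptr %% capacity + 1L
    s[ptr, ] <- .in_s
    s2[ptr, ] <- .in_s2
    a[ptr] <- .in_a
    r[ptr] <- .in_r
    d[ptr] <- .in_d
    size <- min(size + 1L, capacity)
  }, buffer)
  invisible(buffer)
}

#' @rdname replay_buffer
#' @param n batch size.
#' @param rng an [rng_stream()].
#' @export
buffer_sample <- function(buffer, n, rng) {
  if (buffer$size < n) stop("not enough transitions in the buffer")
  idx <- rng_sample_int(rng, buffer$size, n)
  list(s = buffer$s[idx, , drop = FALSE], a = buffer$a[idx],
       r = buffer$r[idx], s2 = buffer$s2[idx, , drop = FALSE],
       d = buffer$d[idx])
}

#' A Soft Actor-Critic agent for discrete actions
#'
#' Holds a categorical policy network, twin soft Q-networks with
#' Polyak-averaged target copies (initialized equal to the locals), Adam
#' optimizer states and a replay buffer. All networks map the flattened
#' sensor-count board (scaled by `1 / n_sensors`) to one output per cell.
#'
#' @param grid `c(H, W)` board dimensions.
#' @param n_sensors sensors per episode (sets the state normalization).
#' @param config a [sac_config()].
#' @return a mutable object of class `sac_agent`.
#' @export
sac_agent <- function(grid = c(20, 7), n_sensors = 8, config = sac_config()) {
  a <- new.env(parent = emptyenv())
  a$grid <- as.integer(grid)
  a$n_actions <- prod(a$grid)
  a$n_sensors <- as.integer(n_sensors)
  a$config <- config
  a$alpha <- config$alpha
  a$rng <- rng_stream(config$seed)
  sizes <- c(a$n_actions, config$hidden, a$n_actions)
  a$policy <- mlp_init(sizes, a$rng)
  a$q1 <- mlp_init(sizes, a$rng)
  a$q2 <- mlp_init(sizes, a$rng)
  a$q1_targ <- a$q1
  a$q2_targ <- a$q2
  a$opt_policy <- adam_init(a$policy)
  a$opt_q1 <- adam_init(a$q1)
  a$opt_q2 <- adam_init(a$q2)
  a$buffer <- replay_buffer(config$buffer_capacity, a$n_actions)
  a$t_total <- 0L         # lifetime agent steps
  a$ep_n <- 0L            # completed episodes; logs preallocated, doubled on demand
  a$ep_rewards_buf <- numeric(1024)
  a$ep_alphas_buf <- numeric(1024)
  class(a) <- "sac_agent"
  a
}

#' @export
print.sac_agent <- function(x, ...) {
  cat(sprintf("<sac_agent> %d x %d board, %d actions, alpha %.4g, %d steps, %d episodes\n",
              x$grid[1], x$grid[2], x$n_actions, x$alpha, x$t_total, x$ep_n))
  invisible(x)
}

# states: matrix batch x n_actions of raw counts, or a single count matrix.
state_input <- function(agent, states) {
  if (is.matrix(states) && identical(dim(states), c(agent$grid[1], agent$grid[2]))) {
    states <- matrix(as.vector(t(states)), 1)   # row-major flatten
  }
  states / agent$n_sensors
}

#' Action probabilities of the policy
#'
#' Softmax over the policy network's logits: a valid probability
#' distribution over the `H * W` cells for each input state.
#'
#' @param agent a [sac_agent()].
#' @param states an H x W count matrix, or a batch of flattened (row-major)
#'   state rows.
#' @return a matrix of probabilities, one row per state.
#' @export
policy_distribution <- function(agent, states) {
  x <- state_input(agent, states)
  logits <- mlp_forward(agent$policy, x)$out
  if (any(!is.finite(logits))) stop("non-finite policy logits")
  softmax_rows(logits)
}

#' Soft state value
#'
#' `V(s) = p' (q - alpha * log p)` for action distribution `p` and
#' action-value vector `q`; probabilities are clamped at 1e-8 inside the
#' log so a deterministic policy contributes exactly zero entropy.
#'
#' @param probs action-probability vector or matrix (rows sum to 1).
#' @param q matching Q-value vector or matrix.
#' @param alpha entropy temperature.
#' @return a numeric vector of state values.
#' @export
soft_state_value <- function(probs, q, alpha) {
  if (!is.matrix(probs)) probs <- matrix(probs, 1)
  if (!is.matrix(q)) q <- matrix(q, 1)
  rowSums(probs * (q - alpha * log(pmax(probs, 1e-8))))
}

#' Target soft Q-values for a batch
#'
#' `y = r + gamma * (1 - done) * V(s')`, where `V(s')` uses the elementwise
#' minimum of the two target Q-networks (clipped double-Q) and the current
#' policy.
#'
#' @param agent a [sac_agent()].
#' @param r reward vector.
#' @param s2 next-state batch (rows = flattened states).
#' @param d numeric done flags (0/1).
#' @return numeric vector of targets, treated as constants by the updates.
#' @export
q_target <- function(agent, r, s2, d) {
  x2 <- state_input(agent, s2)
  p2 <- softmax_rows(mlp_forward(agent$policy, x2)$out)
  q1t <- mlp_forward(agent$q1_targ, x2)$out
  q2t <- mlp_forward(agent$q2_targ, x2)$out
  v2 <- soft_state_value(p2, pmin(q1t, q2t), agent$alpha)
  r + agent$config$gamma * (1 - d) * v2
}

#' One gradient step on the twin Q-networks
#'
#' Minimizes, independently for each Q-network, the mean squared error
#' between `Q(s)[a]` and the target `y` from [q_target()]; the target path
#' carries no gradient.
#'
#' @param agent a [sac_agent()].
#' @param batch a list as returned by [buffer_sample()].
#' @return `c(loss1, loss2)` before the update.
#' @export
update_q <- function(agent, batch) {
  y <- q_target(agent, batch$r, batch$s2, batch$d)
  x <- state_input(agent, batch$s)
  n <- nrow(x)
  sel <- cbind(seq_len(n), batch$a + 1L)
  losses <- numeric(2)
  qouts <- vector("list", 2)
  for (i in 1:2) {
    net_name <- if (i == 1) "q1" else "q2"
    opt_name <- if (i == 1) "opt_q1" else "opt_q2"
    fwd <- mlp_forward(agent[[net_name]], x)
    qouts[[i]] <- fwd$out
    err <- fwd$out[sel] - y
    losses[i] <- mean(err^2)
    d_out <- matrix(0, n, agent$n_actions)
    d_out[sel] <- 2 * err / n
    grads <- mlp_backward(agent[[net_name]], fwd, d_out)
    st <- adam_step(agent[[net_name]], grads, agent[[opt_name]], agent$config$lr)
    agent[[net_name]] <- st$net
    agent[[opt_name]] <- st$opt
  }
  # cache pre-update Q(s) for a policy step on the same batch
  agent$.q_cache <- list(x = x, qmin = pmin(qouts[[1]], qouts[[2]]))
  losses
}

#' One gradient step on the policy
#'
#' Minimizes the expected `p' (alpha * log p - min(Q1, Q2))` over the batch
#' states; the Q-networks are held fixed.
#'
#' @inheritParams update_q
#' @param use_cache reuse the Q(s) values computed by the immediately
#'   preceding [update_q()] call on the same batch (they differ from the
#'   post-update values by one optimizer step); used by the training loop
#'   to avoid two forward passes.
#' @return the policy loss before the update.
#' @export
update_policy <- function(agent, batch, use_cache = FALSE) {
  cache <- if (use_cache) agent$.q_cache else NULL
  x <- if (is.null(cache)) state_input(agent, batch$s) else cache$x
  n <- nrow(x)
  fwd <- mlp_forward(agent$policy, x)
  p <- softmax_rows(fwd$out)
  qmin <- if (is.null(cache)) {
    pmin(mlp_forward(agent$q1, x)$out, mlp_forward(agent$q2, x)$out)
  } else {
    cache$qmin
  }
  g <- agent$alpha * log(pmax(p, 1e-8)) - qmin
  loss <- mean(rowSums(p * g))
  # d loss / d logits for a softmax head: p * (g - E_p[g]) per state
  d_logits <- p * (g - rowSums(p * g)) / n
  grads <- mlp_backward(agent$policy, fwd, d_logits)
  st <- adam_step(agent$policy, grads, agent$opt_policy, agent$config$lr)
  agent$policy <- st$net
  agent$opt_policy <- st$opt
  loss
}

#' Polyak update of the target networks
#'
#' `theta_bar <- tau * theta_bar + (1 - tau) * theta` for both target
#' Q-networks: `tau = 1` freezes the targets, `tau = 0` copies the locals.
#'
#' @param agent a [sac_agent()].
#' @param tau Polyak coefficient; defaults to the agent's configured value.
#' @export
polyak_update <- function(agent, tau = agent$config$tau) {
  mix <- function(targ, loc) {
    for (l in seq_along(targ$w)) {
      targ$w[[l]] <- tau * targ$w[[l]] + (1 - tau) * loc$w[[l]]
      targ$b[[l]] <- tau * targ$b[[l]] + (1 - tau) * loc$b[[l]]
    }
    targ
  }
  agent$q1_targ <- mix(agent$q1_targ, agent$q1)
  agent$q2_targ <- mix(agent$q2_targ, agent$q2)
  invisible(agent)
}

#' Train a SAC-Discrete agent in a placement environment
#'
#' Interleaves environment interaction with gradient updates: sampled
#' actions (uniform during warmup), FIFO replay insertion, and -- every
#' `update_every` agent steps once the buffer holds a batch -- one gradient
#' step on each Q-network, one on the policy, and a Polyak target update.
#' The run is reproducible given the agent's and environment's seeds.
#'
#' @param env a [placement_env()].
#' @param agent a [sac_agent()]; created from `config` if missing.
#' @param steps number of agent (environment) steps to run.
#' @param config used to build `agent` when none is given.
#' @return the agent, invisibly; per-episode rewards accumulate in its log
#'   (see [training_log()] and [episode_rewards()]).
#' @export
sac_train <- function(env, steps, agent = NULL, config = sac_config()) {
  if (is.null(agent)) agent <- sac_agent(env$grid, env$n_sensors, config)
  cfg <- agent$config
  need_reset <- !env$started || env$done
  ep_r <- if (need_reset) 0 else agent$partial_ep_r %||% 0
  s_flat <- if (need_reset) NULL else as.vector(t(env$counts))
  for (i in seq_len(steps)) {
    if (is.null(s_flat)) {
      s <- env_reset(env)
      s_flat <- as.vector(t(s))
      ep_r <- 0
    }
    if (agent$t_total < cfg$warmup) {
      a <- rng_sample_int(agent$rng, agent$n_actions, 1) - 1L
    } else {
      p <- policy_distribution(agent, matrix(s_flat, 1))
      a <- rng_sample_int(agent$rng, agent$n_actions, 1, prob = p[1, ]) - 1L
    }
    out <- env_step(env, a)
    s2_flat <- as.vector(t(out$state))
    buffer_add(agent$buffer, s_flat, a, out$reward, s2_flat, out$done)
    agent$t_total <- agent$t_total + 1L
    ep_r <- ep_r + out$reward
    if (out$done) {
      if (agent$ep_n == length(agent$ep_rewards_buf)) {
        agent$ep_rewards_buf <- c(agent$ep_rewards_buf,
                                  numeric(length(agent$ep_rewards_buf)))
        agent$ep_alphas_buf <- c(agent$ep_alphas_buf,
                                 numeric(length(agent$ep_alphas_buf)))
      }
      agent$ep_n <- agent$ep_n + 1L
      agent$ep_rewards_buf[agent$ep_n] <- env$final_reward
      agent$ep_alphas_buf[agent$ep_n] <- agent$alpha
      s_flat <- NULL
    } else {
      s_flat <- s2_flat
    }
    if (agent$t_total >= cfg$warmup &&
        agent$t_total %% cfg$update_every == 0L &&
        agent$buffer$size >= cfg$batch_size) {
      batch <- buffer_sample(agent$buffer, cfg$batch_size, agent$rng)
      update_q(agent, batch)
      update_policy(agent, batch, use_cache = TRUE)
      polyak_update(agent)
    }
  }
  agent$partial_ep_r <- ep_r
  invisible(agent)
}

#' Per-episode training log of an agent
#'
#' @param agent a [sac_agent()].
#' @return a tibble with `episode`, `reward`, `alpha` and `steps` (agent
#'   steps completed at episode end).
#' @export
training_log <- function(agent) {
  n <- agent$ep_n
  out <- tibble::tibble(episode = seq_len(n),
                        reward = agent$ep_rewards_buf[seq_len(n)],
                        alpha = agent$ep_alphas_buf[seq_len(n)],
                        steps = seq_len(n) * agent$n_sensors)
  class(out) <- c("copsense_log", class(out))
  out
}

#' @rdname training_log
#' @export
episode_rewards <- function(agent) {
  agent$ep_rewards_buf[seq_len(agent$ep_n)]
}

#' Greedy rollout of a trained agent
#'
#' Runs one episode taking the argmax of the policy distribution at every
#' step (ties broken by the lowest cell index).
#'
#' @param agent a [sac_agent()].
#' @param env a [placement_env()].
#' @return `list(placement, reward, actions)` with 0-based `actions`.
#' @export
greedy_rollout <- function(agent, env) {
  s <- env_reset(env)
  actions <- integer(0)
  repeat {
    p <- policy_distribution(agent, matrix(as.vector(t(s)), 1))
    a <- which.max(p[1, ]) - 1L
    actions <- c(actions, a)
    out <- env_step(env, a)
    s <- out$state
    if (out$done) break
  }
  list(placement = env_placement(env), reward = env$final_reward,
       actions = actions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load an agent checkpoint
#'
#' A checkpoint is self-describing: configuration, grid, all network and
#' optimizer parameters, random-stream states, lifetime counters and the
#' episode log, but not the replay buffer (a reloaded agent resumes with
#' an empty buffer). Loading reproduces the saved policy exactly.
#'
#' @param agent a [sac_agent()].
#' @param path file path (RDS format).
#' @export
save_agent <- function(agent, path) {
  ck <- list(
    format = "copsense-agent-1",
    grid = agent$grid, n_sensors = agent$n_sensors, config = agent$config,
    alpha = agent$alpha,
    policy = agent$policy, q1 = agent$q1, q2 = agent$q2,
    q1_targ = agent$q1_targ, q2_targ = agent$q2_targ,
    opt_policy = agent$opt_policy, opt_q1 = agent$opt_q1,
    opt_q2 = agent$opt_q2,
    rng_state = agent$rng$state,
    t_total = agent$t_total, ep_n = agent$ep_n,
    ep_rewards = agent$ep_rewards_buf[seq_len(agent$ep_n)],
    ep_alphas = agent$ep_alphas_buf[seq_len(agent$ep_n)]
  )
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "copsense-agent-1")) stop("not an agent checkpoint")
  agent <- sac_agent(ck$grid, ck$n_sensors, ck$config)
  for (f in c("alpha", "policy", "q1", "q2", "q1_targ", "q2_targ",
              "opt_policy", "opt_q1", "opt_q2", "t_total")) {
    agent[[f]] <- ck[[f]]
  }
  agent$rng$state <- ck$rng_state
  n <- length(ck$ep_rewards)
  agent$ep_n <- as.integer(n)
  agent$ep_rewards_buf <- c(ck$ep_rewards, numeric(max(1024 - n, 0)))
  agent$ep_alphas_buf <- c(ck$ep_alphas, numeric(max(1024 - n, 0)))
  agent
}
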