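test_that("policy outputs valid distributions and seeded sampling repeats", {
  agent <- sac_agent(c(4, 3), 2, sac_config(seed = 5, hidden = 16))
  s <- matrix(0L, 4, 3)
  p <- policy_distribution(agent, s)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))

  # zeroed final layer -> exactly uniform
  agent$policy$w[[length(agent$policy$w)]][] <- 0
  agent$policy$b[[length(agent$policy$b)]][] <- 0
  expect_equal(as.vector(policy_distribution(agent, s)), rep(1 / 12, 12))

  # identical seeds give identical sampled actions
  draw <- function(seed) {
    a <- sac_agent(c(4, 3), 2, sac_config(seed = seed, hidden = 16))
    pr <- policy_distribution(a, s)
    rng_sample_int(a$rng, 12, 5, replace = TRUE, prob = pr[1, ])
  }
  expect_identical(draw(11), draw(11))
})

test_that("soft state value matches hand-computed cases", {
  # uniform over 2 actions, q = 0, alpha = 1 -> entropy log(2)
  expect_equal(soft_state_value(c(0.5, 0.5), c(0, 0), 1), log(2),
               tolerance = 1e-12)
  # alpha = 0 and constant q -> that constant
  expect_equal(soft_state_value(c(0.3, 0.7), c(2, 2), 0), 2)
  # degenerate distribution: clamped log contributes (almost) nothing
  expect_equal(soft_state_value(c(1, 0), c(3, -5), 1), 3, tolerance = 1e-6)
})

test_that("q targets bootstrap with min of targets and respect done/gamma", {
  agent <- sac_agent(c(2, 2), 2, sac_config(seed = 3, hidden = 8,
                                            gamma = 0.9, alpha = 0.01))
  s2 <- matrix(c(1, 0, 0, 0), 1, 4)
  # done = 1 -> y = r regardless of the next state
  expect_equal(q_target(agent, 0.7, s2, 1), 0.7)
  # gamma = 0 -> y = r
  agent0 <- sac_agent(c(2, 2), 2, sac_config(seed = 3, hidden = 8,
                                             gamma = 0, alpha = 0.01))
  expect_equal(q_target(agent0, 0.5, s2, 0), 0.5)
  # scalar arithmetic: y = r + gamma * V(s')
  p2 <- policy_distribution(agent, s2)
  q1 <- mlp_forward(agent$q1_targ, s2 / agent$n_sensors)$out
  q2 <- mlp_forward(agent$q2_targ, s2 / agent$n_sensors)$out
  v2 <- soft_state_value(p2, pmin(q1, q2), agent$alpha)
  expect_equal(q_target(agent, 0.5, s2, 0), 0.5 + 0.9 * v2)
})

test_that("polyak update follows the printed orientation", {
  agent <- sac_agent(c(2, 2), 1, sac_config(seed = 1, hidden = 4))
  # targets start equal to locals
  expect_identical(agent$q1_targ$w, agent$q1$w)
  agent$q1$w[[1]][] <- 1
  agent$q1_targ$w[[1]][] <- 0

  polyak_update(agent, tau = 1)     # tau = 1: targets frozen
  expect_true(all(agent$q1_targ$w[[1]] == 0))
  polyak_update(agent, tau = 0.995) # one step: 0.995*0 + 0.005*1
  expect_equal(agent$q1_targ$w[[1]][1, 1], 0.005, tolerance = 1e-12)
  polyak_update(agent, tau = 0)     # tau = 0: copy locals
  expect_true(all(agent$q1_targ$w[[1]] == 1))
})

test_that("q updates reduce error on a fixed batch", {
  agent <- sac_agent(c(2, 2), 2, sac_config(seed = 2, hidden = 16, lr = 1e-2))
  withr::with_seed(1, {
    batch <- list(s = matrix(sample(0:2, 40, TRUE), 10, 4), a = sample(0:3, 10, TRUE),
                  r = runif(10), s2 = matrix(sample(0:2, 40, TRUE), 10, 4),
                  d = rep(1, 10))  # done: targets are just r, fixed
  })
  l0 <- update_q(agent, batch)
  for (i in 1:60) l <- update_q(agent, batch)
  expect_lt(l[1], l0[1] / 10)
  expect_lt(l[2], l0[2] / 10)
})

test_that("the converged one-state policy is softmax(Q/alpha)", {
  # single state, all actions terminal with fixed rewards: Q* = r.
  # The entropy-regularized optimum is pi = softmax(Q*/alpha).
  grid <- c(1, 3)
  alpha <- 0.5
  q_star <- c(1, 0, 0.5)
  agent <- sac_agent(grid, 1, sac_config(seed = 4, hidden = 16, lr = 3e-3,
                                         alpha = alpha))
  s <- matrix(0, 1, 3)
  batch <- list(s = s[rep(1, 16), ], a = rep(0:2, length.out = 16),
                r = q_star[rep(1:3, length.out = 16)],
                s2 = s[rep(1, 16), ], d = rep(1, 16))
  batch$r <- q_star[batch$a + 1]
  for (i in 1:800) {
    update_q(agent, batch)
    update_policy(agent, batch)
  }
  p <- policy_distribution(agent, matrix(0L, 1, 3))
  expected <- exp(q_star / alpha) / sum(exp(q_star / alpha))
  expect_lt(0.5 * sum(abs(p - expected)), 1e-2)  # total variation
})

test_that("policy limits: large alpha flattens, small alpha concentrates", {
  grid <- c(1, 2)
  s <- matrix(0, 1, 2)
  run_policy <- function(alpha) {
    agent <- sac_agent(grid, 1, sac_config(seed = 6, hidden = 8, lr = 5e-3,
                                           alpha = alpha))
    # pin the Q-networks to a fixed gap by training them on terminal rewards
    batch <- list(s = s[rep(1, 8), ], a = rep(0:1, 4),
                  r = rep(c(1, 0), 4), s2 = s[rep(1, 8), ], d = rep(1, 8))
    for (i in 1:500) update_q(agent, batch)
    for (i in 1:2000) update_policy(agent, batch)
    policy_distribution(agent, matrix(0L, 1, 2))[1, ]
  }
  p_hot <- run_policy(50)
  expect_equal(p_hot, c(0.5, 0.5), tolerance = 0.02)
  p_cold <- run_policy(0.01)
  expect_gt(p_cold[1], 0.98)
})

test_that("replay buffer is FIFO with uniform in-batch sampling", {
  b <- replay_buffer(4, 2)
  for (i in 1:6) buffer_add(b, c(i, i), i %% 2, i / 10, c(i, i), i == 6)
  expect_equal(b$size, 4L)
  # transitions 1 and 2 were overwritten
  expect_setequal(b$s[, 1], 3:6)
  rng <- rng_stream(2)
  batch <- buffer_sample(b, 3, rng)
  expect_equal(nrow(batch$s), 3)
  expect_false(any(duplicated(batch$s[, 1])))  # without replacement
  expect_error(buffer_sample(replay_buffer(4, 2), 1, rng), "not enough")
})

test_that("training cadence and determinism hold on a tiny instance", {
  mk_env <- function(seed) tiny_env(seed = seed, n_sensors = 2)
  cfg <- sac_config(seed = 7, hidden = 8, warmup = 4, update_every = 100,
                    batch_size = 4, buffer_capacity = 50)
  agent <- sac_agent(c(2, 2), 2, cfg)
  sac_train(mk_env(1), 8, agent = agent)
  expect_equal(agent$buffer$size, 8L)
  expect_equal(agent$opt_q1$t, 0L)  # update_every > steps: no gradient step

  run_log <- function() {
    a <- sac_agent(c(2, 2), 2, sac_config(seed = 7, hidden = 8, warmup = 10,
                                          update_every = 2, batch_size = 4))
    sac_train(mk_env(3), 400, agent = a)
    episode_rewards(a)
  }
  expect_identical(run_log(), run_log())
})

test_that("agent checkpoints round-trip the policy and training state", {
  env <- tiny_env(2, n_sensors = 2)
  agent <- sac_train(env, 300, config = sac_config(seed = 9, hidden = 8,
                                                   warmup = 20,
                                                   update_every = 4,
                                                   batch_size = 8))
  path <- withr::local_tempfile(fileext = ".rds")
  save_agent(agent, path)
  back <- load_agent(path)
  s <- matrix(0L, 2, 2)
  expect_identical(policy_distribution(back, s), policy_distribution(agent, s))
  expect_identical(back$t_total, agent$t_total)
  expect_identical(episode_rewards(back), episode_rewards(agent))
  expect_identical(back$alpha, agent$alpha)
  # the reloaded agent keeps training from the saved RNG state
  expect_identical(rng_runif(back$rng, 3), rng_runif(agent$rng, 3))
})

test_that("training solves a brute-force-verifiable tiny placement problem", {
  f <- matrix(0, 2, 2); f[1, 1] <- 1; f[2, 2] <- 4
  v <- pressure_video(array(f, dim = c(2, 2, 1)))
  opt <- brute_force_optimal(v, 1)
  env <- placement_env(v, n_sensors = 1, seed = 2)
  agent <- sac_train(env, 3000,
                     config = sac_config(seed = 1, hidden = 16, warmup = 200,
                                         update_every = 2, alpha = 0.01))
  g <- greedy_rollout(agent, env)
  expect_equal(g$reward, opt$value, tolerance = 1e-9)
})
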