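---
title: "Sensor placement for center-of-pressure fitting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor placement for center-of-pressure fitting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(copsense)
```

## The problem

Insole pressure-measurement systems with a handful of discrete sensors are
far cheaper and more wearable than full-matrix systems, but their usefulness
depends on where the sensors sit. `copsense` designs a placement of `n`
sensors (default 8) on a discretized plantar region (default 20 x 7 cells,
rows along the anteroposterior axis) such that the center of pressure (COP)
computed from only the sensed cells tracks the COP of the full pressure
field over time. The search space is huge -- `140^8 > 1.16e17` ordered
placements -- so the package treats placement as a sequential decision
problem and solves it with maximum-entropy reinforcement learning.

## The reward model

For a pressure video with frames indexed `n = 0..N`, the COP of frame `n`
is the pressure-weighted mean of the 0-based cell coordinates. A placement
masks the video cell-wise (cells without a sensor read zero; several
sensors on one cell act as one), and the fit of the masked COP trajectory
is scored as

    reward = (1 - mean(d_n) / maxdistance)^0.4,
    maxdistance = sqrt(W^2 + H^2),

where `d_n` is the per-frame Euclidean distance between the full-field and
masked COP. The reward lives in [0, 1] and equals 1 exactly when the masked
trajectory reproduces the full trajectory on every frame. The exponent 0.4
expands resolution near perfect fits, so late improvements remain visible
to a learner. Two degenerate cases need conventions, chosen so that the
extremes behave sensibly:

* frames whose *full-field* COP is undefined (zero total pressure, e.g. the
  empty lead-in/lead-out frames of a recording) are skipped -- excluded
  from the mean -- so an otherwise perfect placement still scores exactly 1;
* frames where only the *masked* COP is undefined (the placement captures
  no pressure) are charged the maximal distance, so the empty placement
  scores exactly 0.

`maxdistance` uses the grid dimensions (7 and 20, giving `sqrt(449)`), read
as cell counts rather than maximal index differences.

## The placement environment and reward redistribution

An episode starts from an empty board and a video drawn uniformly from the
dataset; each step places one sensor on one of the `H*W` cells (repeats
allowed); the episode ends after exactly `n_sensors` steps. In the raw
formulation the only nonzero reward arrives at the terminal state, which is
a hard delayed-credit problem. Because the accumulative reward of any
placement prefix can be evaluated in closed form, the terminal reward is
redistributed exactly: with `A_t` the episode reward of the first `t`
placements (`A_0 = 0`), step `t` earns `r_t = A_t - A_{t-1}`. The
telescoping sum guarantees `sum(r_t)` equals the terminal reward to
floating-point precision; a step onto an already covered cell earns 0, and
a step that drags the masked COP away from the truth earns a negative
reward. Terminal-mode rewards are retained as an ablation
(`reward_mode = "terminal"`).

## The agent

The agent is a Soft Actor-Critic for discrete actions: a categorical policy
`pi(a | s)` and twin soft Q-functions with Polyak-averaged target copies.
The target value uses the elementwise minimum of the two target networks
(clipped double-Q), and the printed Polyak orientation
`theta_bar <- tau * theta_bar + (1 - tau) * theta` is implemented verbatim,
so `tau` close to 1 means slow target drift. The policy minimizes
`E_s[ pi(s)' (alpha * log pi(s) - min(Q1, Q2)(s)) ]`; probabilities are
clamped at `1e-8` inside logarithms so a deterministic policy has exactly
zero entropy. With `alpha -> 0` the objective reduces to the standard
expected return.

### Network architecture

Both the policy and the Q-functions are single-hidden-layer perceptrons
(140 -> 128 ReLU -> 140) over the flattened sensor-count board, scaled by
`1 / n_sensors`; counts are not binarized, so the board observation
uniquely determines the remaining-sensor budget. A convolutional encoder
was considered and rejected: the environment observation contains only the
board (not the pressure image), so per-cell value structure is inherently
position-specific and translation-invariant feature sharing buys little,
while costing roughly an order of magnitude per gradient step in this
CPU-only implementation. Hidden sizes are configurable
(`sac_config(hidden = ...)`).

### Discount factor

The default discount is deliberately small (`gamma = 0.1`). With exact
accumulative-reward differencing, each step's redistributed reward already
carries that action's full credit -- the idea behind return decomposition:
when the redistribution is exact, expected future corrections vanish and
near-myopic value estimation is unbiased while dramatically sharpening the
per-action advantage signal. With `gamma` near 1, the Q-gap between a good
and a wasted placement nearly cancels (the future recovers almost all of
the loss), pushing required Q-precision below what is reachable at small
step budgets. For terminal-mode training (no redistribution), `gamma` must
be set near 1 for credit to propagate at all; `sac_config(gamma = 0.99)`
is recommended there.

### Other defaults

Values stated by the reference protocol: Adam learning rate `3e-4`;
temperature initialization log-uniform on `[1e-3, 1e-1]` under
population-based training; perturbation factors 0.8/1.2; evaluation as the
mean of the last 10 episodic rewards. Values this package chose (exposed in
`sac_config()`): batch 64, replay capacity `1e5` (FIFO), one gradient step
per 4 agent steps (half an episode), 1000 warmup steps of uniform-random
actions, Polyak `tau = 0.995`. The temperature default for stand-alone (non-PBT) training
is `4e-3`, the value the temperature-sweep experiment identifies as a good
fixed setting.

## Population-based training

`run_population()` trains a population (reference size 15) whose members
differ in entropy temperature. Members are evaluated by the trailing mean
of 10 episodic rewards; a member at least `ready_interval` agent steps past
its last ready event undergoes exploit/explore: if it ranks in the bottom
`ceiling(0.2 * N)` members it copies the networks and temperature of a
uniformly drawn top-`ceiling(0.2 * N)` member and multiplies the
temperature by 0.8 or 1.2. Scheduling is synchronous round-robin in slices
of `slice_steps` agent steps, which makes whole runs bit-reproducible on
one machine; an asynchronous scheduler would not be. Ranking ties break by
member index; exploit never changes a member outside the bottom set, and a
member that is simultaneously in the top and bottom cut (tiny populations)
is left unchanged.

## Synthetic data

No public plantar-pressure dataset accompanies the reference protocol, so
the package generates its study conditions:

* `make_testing_video()` -- a structured validation video on the 20 x 7
  grid: empty first and last frames, and in between at most 8 support
  cells whose magnitudes ramp up and back down (triangular profiles,
  phase-shifted along the support path so the COP travels
  anteroposteriorly). Because the support is within the sensor budget, a
  placement covering it reproduces the COP exactly and the attainable
  episode-reward maximum is exactly 1 -- the property the validation
  experiment relies on.
* `make_gait_video()` -- one synthetic stance phase: a 2D Gaussian pressure
  blob translating heel to toe with a double-hump (impact / push-off)
  total-force profile and multiplicative noise, seeded and deterministic.
  `make_gait_dataset()` draws per-video geometry from modest ranges to
  emulate between-stride variation.

What the generators do *not* emulate: anatomical pressure distributions
(metatarsal-head structure, arch shape), sensor noise floors, calibration
drift, or between-subject anatomy. Results on synthetic data therefore
validate the *method* (environment, reward, learning dynamics), not any
claim about real feet.

`brute_force_optimal()` provides an independent oracle on small instances
by exhaustive subset enumeration; because the reward masks by the support
of the counts, duplicate sensors never help and subset enumeration covers
the full multiset space. The default cap refuses instances beyond `1e6`
combinations.

## Scaled experiment protocols

The reference protocol trains a population of 15 for 10M agent steps
(1.25M episodes of 8 steps). That scale is far beyond a desk run in this
implementation, so the packaged experiments are scaled down with the same
structure, and the scaling is part of the package's stated protocol:

* *testing-video run*: population 3, 2e5 total agent steps, ready interval
  1e4 member steps, slices of 2e3 (the ready interval keeps the same ~5%
  proportion of the per-member budget as 5e5 is of the reference run).
* *temperature sweep*: fixed temperatures `1e-3` vs `4e-3` compared over 3
  paired seeds at 1.5e4 agent steps per run, mirroring the structure (not
  the scale) of the reference comparison.
* *gait-dataset run*: 20 synthetic stance videos in place of the
  unavailable 150-video dataset; 1e5 total agent steps for the packaged
  dominance comparison, with `gamma = 0.99` (unlike the testing-video run,
  competing against strong spatially distributed layouts rewards
  non-myopic placement, so credit must cross steps).

At these budgets the best member reliably reaches greedy-rollout rewards
in the 0.97-0.99 range on the testing video (0.9922 at seed 1, with the
population's temperatures annealing into the 3.5e-3 to 4.5e-3 region);
reaching the exact maximum of 1.0 within floating-point tolerance, as the
full-scale protocol reports after 50 times more training, is not
consistently attained -- the remaining gap concentrates in late placement
steps whose marginal rewards are on the order of 1e-2, where
policy-gradient recovery from a transiently collapsed probability is
proportional to that (near-zero) probability. For the same reason the
fixed-temperature sweep is a statistical dead heat at desk scale: the
mean final moving-average rewards of the two temperatures differ by less
than 1e-2 across paired seeds, with the separation expected only at
budgets far beyond a desk run. Likewise, on the synthetic gait dataset
the learned placements reach mean rewards of 0.96-0.98 at desk budgets,
short of a well-spread fixed two-column reference layout (0.985) even
though exhaustively better placements exist (a midline layout scores
0.994): the shortfall is the same late-step pathology, not a property of
the reward model.

## Numerical choices

* Force-conserving downsampling distributes each source cell's force over
  target bins by exact geometric overlap; per-frame force is conserved to
  1e-9 relative, and uniform fields are fixed points.
* Distances are capped at `maxdistance` (reachable distances are always
  smaller; the cap guards rounding).
* `A_0 = 0` for redistribution coincides with the empty-placement reward,
  so no special-casing is needed at `t = 1`.
* All randomness flows through seeded, mutually independent streams
  (`rng_stream`), so environments, agents and populations are reproducible
  individually and jointly.
* Brute-force ties are grouped at 1e-12 absolute and reported in
  lexicographic order.

## Known limitations

* Evaluation uses sampled (not greedy) episodes, matching the stated
  protocol; at small population sizes this lets low-temperature members
  outrank better-exploring ones, which can herd the population early.
* The synchronous scheduler serializes member training; it trades the
  reference's asynchronous parallelism for exact reproducibility.
* The generators produce single-foot stance videos only; bilateral
  comparisons and real calibrated recordings are out of scope.
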