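# copsense

Design sparse plantar-pressure sensor layouts that reproduce the
center-of-pressure (COP) trajectory of full-resolution plantar pressure
recordings.

Wearable insoles with a handful of discrete pressure sensors are cheap and
unobtrusive, but their value hinges on where the sensors sit. Given stance
phase pressure videos on a 20 x 7 grid (rows along the foot's long axis),
`copsense` searches for a placement of 8 sensors whose *masked* COP
trajectory — the COP computed from only the sensed cells — tracks the
full-field COP. With 140 cells and 8 ordered placements the search space
exceeds 10^17, so the package treats placement as a sequential decision
problem and solves it with maximum-entropy reinforcement learning.

## The model

For frames `n = 0..N`, the COP is the pressure-weighted centroid of the
cell coordinates. A placement masks the video cell-wise, and its episode
reward is

```
reward = (1 - mean(d_n) / maxdistance)^0.4 ,   maxdistance = sqrt(W^2 + H^2)
```

with `d_n` the per-frame distance between the full and masked COP; the
reward lies in [0, 1] and is 1 exactly when the masked trajectory is
perfect. An episode of the placement environment puts one sensor per step
for 8 steps; the delayed terminal reward is *redistributed* exactly over
the steps by differencing prefix rewards (`r_t = A_t - A_{t-1}`,
telescoping to the terminal value), which turns a hard delayed-credit task
into a dense one. The agent is a Soft Actor–Critic for discrete actions
(categorical policy, twin soft Q-networks, clipped double-Q targets,
Polyak-averaged target copies), and the entropy temperature is tuned by
population-based training: underperforming members copy a top member's
networks and temperature and perturb the temperature by 0.8 or 1.2.

## Worked example

Train a small population on the structured testing video (empty first and
last frames, ramped magnitudes on 8 support cells, attainable maximum
reward exactly 1) and inspect the result:

```r
library(copsense)

cfg <- config_testing_experiment(seed = 1, total_steps = 2e5)  # population of 3
res <- run_experiment(cfg, "runs/testing-seed1")
print(res)
#> <copsense_run> 200,000 steps, best member 3: perf 0.9798, greedy reward 0.9922

tidy(res)
#> # A tibble: 3 x 5
#>   member episodes   alpha  perf best
#>    <int>    <int>   <dbl> <dbl> <lgl>
#> 1      1     8500 0.00341 0.978 FALSE
#> 2      2     8250 0.00426 0.976 FALSE
#> 3      3     8250 0.00355 0.980 TRUE
```

`perf` is each member's mean over its last 10 (sampled) episodic rewards;
`greedy reward` is the episode reward of the best member's deterministic
rollout — here 0.9922 of the attainable 1.0 after 2e5 agent steps, about
1/50th of the reference training budget (at full scale the protocol
converges to the maximum). The temperatures were initialized log-uniformly
on [1e-3, 1e-1] and annealed by exploit/explore into the 3e-3 to 5e-3
region. The run directory contains the per-episode JSONL log,
moving-average reward curves, the final placement as JSON, and reward /
temperature figures.

Other entry points: `preprocess_video()` (stance splitting, representative
selection, border cropping, force-conserving downsampling of raw
recordings), `episode_reward()` / `redistribute_rewards()` (the reward
model), `brute_force_optimal()` (exhaustive oracle for small instances),
`evaluate_placement()` (mean reward of any fixed layout over a video set),
and a thin command-line interface in `exec/copsense`
(`generate`, `preprocess`, `oracle`, `evaluate`, `train`).

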