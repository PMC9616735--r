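---
title: "Modelling flexible maze navigation with tabular RL agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling flexible maze navigation with tabular RL agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazerl)
```

## The task and the modelling problem

`mazerl` models goal-directed navigation in a reconfigurable open-field maze:
a 10 x 10 grid of modules, one of which hides a fixed goal. Between blocks of
trials, modules are removed to form impassable barriers, forcing detours and
opening shortcuts. Subjects (rats, humans in VR, or simulated agents) run a
fixed sequence of configurations — by default 25 configurations of 10 trials
each — starting each trial from a prescribed location, with 45 moves
available per trial (one module transition per second within a 45 s limit).
A subject can only see its adjacent modules (fog), plus a distal cue that
fixes the reference frame, so adapting to a new layout requires exploration.

The scientific question the package operationalises is *which learning
algorithm best explains the observed trajectories*. Three classic tabular
reinforcement learners span the space of hypotheses:

* **Model-free (MF)** — Q-learning with an eligibility trace. A table
  `Q(s, a)` caches the discounted value of taking action `a` (up, down,
  left, right) in module `s`. After each transition the whole trace decays,
  `e <- lambda * gamma * e`, the visited pair is incremented,
  `e(s_t, a_t) <- e(s_t, a_t) + 1`, and every entry moves by the TD error
  scaled by its trace:
  `Q <- Q + alpha * (r_t + gamma * max_a Q(s_{t+1}, a) - Q(s_t, a_t)) * e`.
  Reward is 1 on the transition into the goal, which also terminates the
  episode (bootstrap term 0). MF has no transition model, so after a layout
  change it keeps marching into walls its cached values recommend.
* **Successor representation (SR)** — a predictive map `M(s, s')`, the
  expected discounted number of future visits to `s'` from `s` under the
  current behaviour, learned by TD with a state trace:
  `M <- M + alpha * e %o% (1_{s_t} + gamma * M(s_{t+1}, ) - M(s_t, ))`.
  Value is the inner product of a row of `M` with the reward vector, which
  in this task is the goal indicator, so `V(s) = M(s, goal)`. The SR adapts
  faster than MF because one relearned row reshapes value everywhere
  upstream, but it still learns from experience rather than planning.
* **Model-based (MB)** — a binary internal map `chi` of which modules are
  present, overwritten by direct observation of the (at most four) adjacent
  modules at every step. At decision time the agent plans the shortest route
  from each candidate next state to the goal through `chi` (A*/breadth-first
  search; both are exact on a unit 4-connected lattice). MB adapts as fast
  as its observations allow but plans through stale beliefs about parts of
  the maze it has not revisited.

For a one-step transition matrix `T` of a fixed policy the SR has the closed
form `M = I + gamma T + gamma^2 T^2 + ... = (I - gamma T)^{-1}`
(`sr_closed_form()`). The package adopts the episodic convention throughout:
episodes end on goal entry, so the goal row of `T` is zeroed before
inversion, the goal row of `M` is pinned to the goal's one-hot, and
`V(s) = gamma^{d(s)}` exactly, with `d` the shortest-path distance. This
convention keeps the three agents' values on a common `[0, 1]` scale.

## Initialization: the training phase

Subjects are trained to criterion on the fully open maze before testing.
Agents emulate that phase analytically (`initialize_agent()`): MF receives
`Q(s, a) = gamma^{d(s')}` for the successor `s'` of each action, SR receives
the closed-form `M` of the open-maze optimal policy (ties among optimal
actions averaged), and MB starts with `chi` all ones. Under a greedy policy
every kind then walks an exact shortest path from any start — an invariant
the test suite checks for all 99 non-goal starts.

## Fitting agents to trajectories

`forced_walk_loglik()` walks an agent along a subject's observed state
sequence in experiment order. At each step the candidate set is the truly
available transitions; the agent's current values feed a softmax with
inverse temperature `beta`, the log-probability of the observed choice is
accumulated, and only then is the agent's learning rule applied to the
observed transition (MB also observes adjacency at every state it enters,
including each trial's start). Representations persist across trials and
configurations; each trial starts with a zeroed eligibility trace. Nothing
downstream of a step influences its likelihood.

`fit_parameters()` maximises this likelihood over the learning rate
`alpha` in `[0, 1]` and discount `gamma` in `[0, 0.99]` (MB has only
`gamma`; its map update has no learning rate) by multi-start L-BFGS-B, with
starts on a fixed van der Corput grid so fits are deterministic. Numerical
choices that matter:

* `gamma` is capped at 0.99 to keep `gamma^d` contrasts finite and the SR
  inversion well-conditioned.
* a per-step probability floor of `1e-12` keeps the log-likelihood finite
  under extreme parameter proposals; applications are counted and reported.
* `beta` and `lambda` are not fitted. `lambda = 0.5` is the task convention;
  `beta = 1` is the package's default convention for biological data, where
  the true choice temperature is unknown. When the generating temperature
  *is* known (synthetic cohorts), conditioning the fit on it is both
  legitimate and advisable.
* the MB decision value is `gamma^{d_chi(s')}`, a monotone transform of the
  planned path length. This makes `gamma` the MB model's single parameter,
  puts MB values on the same scale as MF and SR, and under greedy choice
  reproduces equal-probability sampling among equally short planned routes.
  A candidate its model disconnects from the goal is valued 0.

`normalize_loglik()` expresses a trial's fit per step relative to a uniform
random walk over the available transitions (0 = chance, `log 2` = twice
chance per step), and `compare_models()` produces pairwise log
likelihood-ratios and per-trial best-model labels, with exact ties labelled
rather than silently broken.

## Simulating fitted agents

`run_experiment()` mirrors the study's simulation protocol. For each
configuration `k`, an agent of each kind is trained by replaying the
subject's own trajectories on configurations `1..k-1` (identical mechanics
to the likelihood pass, no likelihood accumulated), then 100 independent
replicate clones run the 10 trials of configuration `k` under an
epsilon-greedy policy decaying linearly from 0.1 to 0.01 across trials
(`epsilon_for_trial()`), learning as they go and carrying representations
across the configuration's trials. A trial ends on goal entry or at the
45-transition cap; a capped trial keeps its learning and the next trial
starts from the next scheduled location. Every replicate derives its RNG
stream from the master seed via `child_seed()`, so runs are bytewise
reproducible.

## Trajectory analytics

* **Occupancy** (`occupancy_map()`): proportion of step-samples per module;
  compared between groups by Pearson correlation.
* **Deviation from optimal** (`deviation_from_optimal()`): extra module
  visitations relative to a shortest path, reported only for goal-reached
  trials; failures are reported separately as goal rates.
* **Diffusivity** (`diffusivity_features()`): the field describes these
  route-shape summaries only loosely, so the package fixes concrete,
  unit-tested definitions and isolates them behind one function so
  alternates can be swapped: `D_lin = |r_end - r_start|^2 / (4 n_steps)`
  (the 2-D mean-squared-displacement convention, module² per step), and the
  sine and cosine of the circular mean of step headings in the maze frame
  (east = 0, north = towards the cue side). Exactly cancelling headings
  leave the angular features undefined (`NA`), and they are dropped from
  per-configuration means.
* **Mahalanobis dissimilarity** (`mahalanobis_dissimilarity()`): distance of
  a subject's per-configuration feature vector from the cloud of replicate
  feature vectors, using the replicates' covariance; a near-singular
  covariance (e.g. near-deterministic MB replicates) is regularised by
  `1e-6` on the diagonal, with a message.
* **Minimum path-distance similarity** (`min_path_distance_similarity()`):
  at every time point of a reference trajectory, the shortest on-maze
  distance to the nearest module the replicate visited, averaged along the
  reference and then over replicates. Distances from states disconnected
  from a replicate's trajectory are capped at maze diameter + 1 so means
  stay finite; occurrences are counted.
* **Difficulty rankings** (`difficulty_rankings()`): Spearman correlation
  (average ranks on ties) between subject and agent per-configuration goal
  rates, with Fisher's `z = atanh(rho)` exposed for paired comparisons
  (`paired_t()`).

## The synthetic-data generator

Real trajectories live in an external deposit; the generator supplies
statistically analogous materials so the whole pipeline is testable
self-contained.

`generate_maze_sequence()` carves straight wall segments (3-7 modules) into
the open grid until a target removal density (default 0.25-0.40) is reached,
rejection-sampling until the goal is reachable from enough edge modules and
the layout truly blocks the direct route: every candidate start must require
tortuosity (path length / Euclidean distance) of at least 1.4 and the
hardest at least 2.0. Starts are drawn one per tortuosity-quantile bin and
ordered so difficulty is non-decreasing across a configuration's trials,
as in the task. These thresholds were chosen so that simulated agents'
goal-reaching rates fall in the range the biological task elicits; with
scattered single-module removals instead, every agent succeeds nearly
always and no trial-wise structure exists to analyse. The generator refuses
(with an error) rather than silently relaxing constraints when the retry
budget is exhausted.

`generate_subject()` rolls a ground-truth agent through a schedule with
softmax(`beta`) or decaying epsilon-greedy choice plus a lapse (uniform
random choice with probability 0.05 by default), learning continuously.
`make_cohort()` samples subject parameters uniformly (`alpha` 0.05-0.3,
`gamma` 0.6-0.95) and defaults to `beta = 5`, calibrated so surrogate
subjects reach the goal on roughly 60-80% of trials — the range real
subjects exhibit; `beta = 1` produces near-random walkers no biological
cohort resembles. Parameter-recovery checks deliberately keep a `beta = 1`
subject as the harder, low-signal case.

What the generator does *not* emulate: species-specific biases
(wall-following, grooming pauses, predator avoidance), continuous
kinematics, within-trial timing, and the original study's pilot-based
criterion of maximising layout differences between consecutive
configurations. Passing the synthetic self-tests therefore demonstrates
that the estimation and comparison machinery is correct and identifiable
under the task's statistical structure — not that any particular biological
population is SR-like.

## Self-tests and the problem sizes they use

The acceptance suite (also re-runnable via `scripts/acceptance.R`) checks,
with fixed seeds:

* shortest-path lengths against an independent breadth-first oracle on 200
  random configurations;
* TD-learned SR convergence to `(I - gamma T)^{-1}` on a 4 x 4 random-walk
  maze (`alpha = 0.1`, `gamma = 0.9`, `lambda = 0.5`). Constant-step TD
  fluctuates around its fixed point rather than converging pathwise, so the
  check evaluates the average of the iterates after a burn-in (100,000
  episodes, 10,000 burn-in) — the standard estimator for constant-step
  stochastic approximation — at an entrywise tolerance of 0.05;
* initialization optimality for all three kinds from all 99 starts;
* recovery of SR parameters (`alpha = 0.1`, `gamma = 0.9`) within 0.15 from
  one synthetic subject on the full 25 x 10 schedule;
* model identification on a cohort of 6 subjects per generating kind on a
  5-configuration schedule, requiring the generating kind to win the total
  log-likelihood for at least two-thirds of subjects;
* the qualitative performance signature on 5-configuration schedules over
  10 seeds (8 replicates each): MB and SR goal-reaching higher on trials
  6-10 than 1-5, MF lower;
* the similarity signature on a 4-configuration schedule with 30 replicates:
  an SR-generated subject is closer in Mahalanobis diffusivity distance to
  its own SR replicate cluster than to the MF cluster, and its minimum
  path-distance similarity is smallest to the SR replicates. Subject and
  replicates share the epsilon-greedy policy here, because comparing a
  subject with replicate distributions is a like-for-like comparison only
  under a common choice policy.

The smaller-than-protocol schedules in the later checks are the package's
own choice to keep the self-tests quick; every mechanism they exercise is
size-independent.

## Known limitations

* All analysis is in discretised module space; continuous kinematics are
  out of scope.
* The likelihood treats `beta` as known; jointly fitting `beta` with
  `alpha` and `gamma` is not supported (they trade off strongly in this
  value parameterisation).
* MB planning assumes unobserved modules are present until seen absent
  (optimistic initialization); alternative priors would change early-trial
  MB behaviour.
* The diffusivity definitions are a documented stand-in for loosely
  specified route-shape summaries; conclusions that hinge on their exact
  form should vary them (the operation is isolated for that purpose).
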