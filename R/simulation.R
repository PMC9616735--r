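# Per-individual agent simulation: train on the individual's history, then
# roll out replicates under a decaying epsilon-greedy policy.

#' Exploration rate for a trial within a configuration
#'
#' Linearly decays from `eps_start` on the first trial to `eps_end` on the
#' last: with the defaults, `epsilon = 0.1 - 0.01 * (trial - 1)` over 10
#' trials, i.e. the agent exploits 90% of the time on trial 1 and 99% on
#' trial 10.
#'
#' @param trial Trial index within the configuration (1-based).
#' @param n_trials Trials per configuration (default 10).
#' @param eps_start,eps_end Endpoints of the linear decay.
#' @return The exploration rate for that trial.
#' @export
epsilon_for_trial <- function(trial, n_trials = 10L, eps_start = 0.1,
                              eps_end = 0.01) {
  if (any(trial < 1L | trial > n_trials)) {
    stop("trial index must lie in 1..", n_trials)
  }
  if (n_trials == 1L) return(rep(eps_start, length(trial)))
  eps_start + (trial - 1) * (eps_end - eps_start) / (n_trials - 1)
}

#' Run one trial of an agent acting in a maze
#'
#' The agent starts at `start`, chooses among the locally available
#' transitions under `policy`, applies its learning update after every step
#' (the MB agent also observes adjacency on entering each state, including the
#' start), and stops on goal entry or at the step cap. Eligibility traces are
#' reset at the trial start. If the start is isolated (no available
#' transition) the trial ends immediately.
#'
#' @param agent An `rl_agent`.
#' @param maze The true `maze_config`.
#' @param start Start state.
#' @param step_cap Maximum number of transitions (default 45).
#' @param policy `"egreedy"` or `"softmax"`.
#' @param epsilon,beta Policy parameters (`beta` defaults to the agent's).
#' @param lapse Probability of replacing the policy distribution by a uniform
#'   choice on a step (default 0).
#' @return List with `trajectory` (a `trajectory`) and `agent` (the updated
#'   agent).
#' @export
run_trial <- function(agent, maze, start, step_cap = 45L,
                      policy = c("egreedy", "softmax"), epsilon = 0.1,
                      beta = agent$params$beta, lapse = 0) {
  policy <- match.arg(policy)
  if (!maze$present[start]) stop("start state is not present in the maze")
  agent <- reset_eligibility(agent)
  agent <- observe_state(agent, start, maze)
  states <- integer(step_cap + 1L)
  states[1L] <- start
  len <- 1L
  s <- start
  while (len <= step_cap && s != maze$goal) {
    cand <- maze$nbr[, s]
    cand <- cand[!is.na(cand)]
    if (!length(cand)) break
    v <- action_values(agent, s, cand, maze)
    p <- choice_distribution(v, policy, beta = beta, epsilon = epsilon)
    if (lapse > 0 && stats::runif(1) < lapse) {
      p <- rep(1 / length(cand), length(cand))
    }
    nxt <- cand[sample.int(length(cand), 1L, prob = p)]
    agent <- agent_step_update(agent, maze, s, nxt)
    len <- len + 1L
    states[len] <- nxt
    s <- nxt
  }
  list(trajectory = trajectory(states[seq_len(len)], maze = maze,
                               validate = FALSE),
       agent = agent)
}

#' Train an agent on a subject's history up to a configuration
#'
#' Initializes the agent on the open maze, then replays the subject's
#' trajectories through configurations `1..upto_config - 1` exactly as in the
#' forced-walk likelihood (same update order, no likelihood accumulation).
#' With `upto_config = 1` the pristine initialized agent is returned.
#'
#' @param params An `agent_params`.
#' @param subject A `subject_data`.
#' @param schedule The `experiment_schedule`.
#' @param upto_config Configuration about to be simulated (1-based, >= 1).
#' @return An `rl_agent`.
#' @export
train_on_history <- function(params, subject, schedule, upto_config) {
  if (upto_config < 1L) stop("upto_config must be >= 1")
  maze1 <- schedule$configs[[1L]]
  open <- open_maze(maze1$nr, maze1$nc, maze1$goal)
  if (upto_config == 1L) return(initialize_agent(params, open))
  sub <- subject
  sub$trials <- subject$trials[seq_len(upto_config - 1L)]
  sched <- make_schedule(schedule$configs[seq_len(upto_config - 1L)],
                         schedule$starts[seq_len(upto_config - 1L)])
  plan <- build_walk_plan(sub, sched)
  continue_walk(initialize_agent(params, open), plan)
}

#' Simulate replicate rollouts of a trained agent on one configuration
#'
#' Each replicate independently clones the trained agent and runs the
#' configuration's trials in order under the decaying epsilon-greedy policy:
#' eligibility reset at each trial start, learning updates after every step,
#' termination on goal entry or at the step cap. Learned representations carry
#' across the trials within the configuration. A trial that hits the cap still
#' applies its updates and the next trial starts from the next scheduled
#' start. Replicate `r` uses the child seed `child_seed(seed, r)`, so outputs
#' are bytewise reproducible.
#'
#' @param agent A trained `rl_agent` (e.g. from [train_on_history()]).
#' @param maze The configuration to simulate.
#' @param starts Integer vector of per-trial start states.
#' @param n_replicates Number of independent replicates (default 100).
#' @param step_cap Maximum transitions per trial (default 45).
#' @param eps_start,eps_end Epsilon-decay endpoints across the trials.
#' @param seed Master seed for this configuration.
#' @return List of length `n_replicates`; each element a list of
#'   `trajectory` objects, one per trial.
#' @export
simulate_configuration <- function(agent, maze, starts, n_replicates = 100L,
                                   step_cap = 45L, eps_start = 0.1,
                                   eps_end = 0.01, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  lapply(seq_len(n_replicates), function(r) {
    set.seed(child_seed(seed, r))
    a <- clone_agent(agent)
    lapply(seq_along(starts), function(t) {
      eps <- epsilon_for_trial(t, length(starts), eps_start, eps_end)
      res <- run_trial(a, maze, starts[t], step_cap = step_cap,
                       policy = "egreedy", epsilon = eps)
      a <<- res$agent
      tr <- res$trajectory
      tr$trial_index <- t
      tr
    })
  })
}

#' Simulate all agent kinds across a subject's full schedule
#'
#' For each configuration `k`, each agent kind is trained on the subject's
#' history over configurations `1..k-1` (training is incremental and
#' deterministic given the history) and then simulated on configuration `k`
#' for `n_replicates` replicates with [simulate_configuration()]. Fitted
#' maximum-likelihood parameters are taken per kind from `fits`.
#'
#' @param subject A `subject_data`.
#' @param fits Named list of `fit_result`s (or `agent_params`) per kind.
#' @param schedule The `experiment_schedule`.
#' @param kinds Agent kinds to simulate (default all three).
#' @param n_replicates Replicates per configuration (default 100).
#' @param step_cap Maximum transitions per trial.
#' @param eps_start,eps_end Epsilon-decay endpoints.
#' @param seed Master seed; child seeds are derived per (kind, configuration,
#'   replicate).
#' @return Object of class `simulation_run`: list with `subject_id`, `seed`,
#'   and `sims[[kind]][[config]]` = replicate trajectory lists.
#' @export
run_experiment <- function(subject, fits, schedule,
                           kinds = c("MF", "MB", "SR"), n_replicates = 100L,
                           step_cap = 45L, eps_start = 0.1, eps_end = 0.01,
                           seed = 1L) {
  missing <- setdiff(kinds, names(fits))
  if (length(missing)) stop("missing fits for kind(s): ",
                            paste(missing, collapse = ", "))
  sims <- stats::setNames(vector("list", length(kinds)), kinds)
  for (kind in kinds) {
    f <- fits[[kind]]
    params <- if (inherits(f, "agent_params")) f else
      agent_params(kind, alpha = if (is.na(f$alpha)) 0 else f$alpha,
                   gamma = f$gamma, lambda = f$lambda, beta = f$beta)
    maze1 <- schedule$configs[[1L]]
    open <- open_maze(maze1$nr, maze1$nc, maze1$goal)
    trainer <- initialize_agent(params, open)
    per_config <- vector("list", length(schedule$configs))
    for (k in seq_along(schedule$configs)) {
      per_config[[k]] <- simulate_configuration(
        trainer, schedule$configs[[k]], schedule$starts[[k]],
        n_replicates = n_replicates, step_cap = step_cap,
        eps_start = eps_start, eps_end = eps_end,
        seed = child_seed(seed, subject$subject_id, kind, k))
      # extend the forced-walk training with this configuration's history
      sub_k <- subject
      sub_k$trials <- subject$trials[k]
      sched_k <- make_schedule(schedule$configs[k], schedule$starts[k])
      plan_k <- build_walk_plan(sub_k, sched_k)
      trainer <- continue_walk(trainer, plan_k)
    }
    sims[[kind]] <- per_config
  }
  structure(list(subject_id = subject$subject_id, seed = seed,
                 n_replicates = n_replicates, sims = sims),
            class = "simulation_run")
}

# Replay a plan through an existing agent (no likelihood tracking).
continue_walk <- function(agent, plan) {
  for (k in seq_along(plan)) {
    maze <- plan[[k]]$maze
    for (t in seq_along(plan[[k]]$trials)) {
      tr <- plan[[k]]$trials[[t]]
      agent <- reset_eligibility(agent)
      if (tr$n_steps > 0L) {
        agent <- observe_state(agent, tr$states[1L], maze)
        for (i in seq_len(tr$n_steps)) {
          agent <- agent_step_update(agent, maze, tr$from[i], tr$to[i])
        }
      }
    }
  }
  agent
}
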