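# Synthetic study materials: barrier-configuration sequences with
# tortuosity-graded starts, and surrogate subjects generated by ground-truth
# agents with known parameters and choice noise.

#' Ground truth for a surrogate subject
#'
#' @param kind Generating agent kind (`"MF"`, `"MB"`, `"SR"`).
#' @param alpha,gamma,beta Agent parameters (see [agent_params()]).
#' @param lapse Probability in \[0, 0.5\] of a uniform-random choice per step,
#'   modelling biological imperfection (default 0.05).
#' @param seed Master seed for the subject's rollouts.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(kind = c("MF", "MB", "SR"), alpha = 0.1, gamma = 0.9,
                         beta = 1, lapse = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  if (lapse < 0 || lapse > 0.5) stop("lapse must lie in [0, 0.5]")
  params <- agent_params(kind, alpha = alpha, gamma = gamma, beta = beta)
  structure(list(kind = kind, params = params, lapse = lapse,
                 seed = as.integer(seed)), class = "ground_truth")
}

#' Generate a sequence of barrier configurations with tortuosity-graded starts
#'
#' Emulates the testing-phase materials: each configuration removes random
#' contiguous wall segments (straight runs of modules, the kind of barrier
#' that blocks direct routes and creates dead ends) under rejection sampling
#' that keeps the goal reachable from at least `n_starts` candidate start
#' modules and forces real detours (the most tortuous available start must
#' reach `min_max_tortuosity`). Starts are drawn from the maze edge (matching
#' the task's pseudo-random edge starts; interior starts optional), one from
#' each quantile bin of the candidates' tortuosity distribution, and ordered
#' so the required tortuosity of the optimal route is non-decreasing across
#' the trials of a configuration. Deterministic given `seed`.
#'
#' @param n_configs Number of configurations (default 25).
#' @param nr,nc Grid dimensions (default 10 x 10).
#' @param goal Goal as 0-based `(row, col)`; fixed across the sequence.
#' @param density_range Range of the fraction of modules removed per
#'   configuration (default 0.25-0.40, which with the tortuosity floors
#'   below yields layouts on which simulated agents reach the goal at rates
#'   comparable to the biological task).
#' @param n_starts Trials (start states) per configuration (default 10).
#' @param edge_starts Restrict start candidates to edge modules (default TRUE).
#' @param min_tortuosity Start candidates must require at least this
#'   tortuosity (default 1.4): every configuration blocks the direct route to
#'   the goal even on its easiest trial, as the task demands.
#' @param min_max_tortuosity Reject layouts whose most tortuous candidate
#'   start falls below this ratio (default 2.0); ensures the later trials
#'   need genuine detours. Set both tortuosity floors to 1 to disable (with
#'   `density_range = c(0, 0)` this yields the open maze and all
#'   tortuosities ~ 1).
#' @param seed RNG seed.
#' @param max_retries Rejection-sampling budget per configuration; exceeding
#'   it is an explicit error, never a silent constraint relaxation.
#' @return An `experiment_schedule`.
#' @export
generate_maze_sequence <- function(n_configs = 25L, nr = 10L, nc = 10L,
                                   goal = c(2L, 7L),
                                   density_range = c(0.25, 0.40),
                                   n_starts = 10L, edge_starts = TRUE,
                                   min_tortuosity = 1.4,
                                   min_max_tortuosity = 2.0,
                                   seed = 1L, max_retries = 1000L) {
  set.seed(child_seed(seed, "mazes"))
  n <- nr * nc
  goal_state <- rc_state(goal[1L], goal[2L], nc)
  rc <- state_rc(seq_len(n), nc)
  on_edge <- rc[, "row"] %in% c(0L, nr - 1L) | rc[, "col"] %in% c(0L, nc - 1L)
  if (any(density_range < 0) || any(density_range >= 1)) {
    stop("density_range must lie in [0, 1)")
  }
  configs <- vector("list", n_configs)
  starts <- vector("list", n_configs)
  for (k in seq_len(n_configs)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      density <- stats::runif(1, density_range[1L], density_range[2L])
      n_rm <- round(density * n)
      pres <- rep(TRUE, n)
      # carve straight wall segments until the density target is met
      guard <- 0L
      while (sum(!pres) < n_rm && guard < 200L) {
        guard <- guard + 1L
        len <- sample(3:7, 1L)
        horiz <- stats::runif(1) < 0.5
        r0 <- sample.int(nr, 1L) - 1L
        c0 <- sample.int(nc, 1L) - 1L
        if (horiz) {
          cc <- c0:min(c0 + len - 1L, nc - 1L)
          seg <- rc_state(rep(r0, length(cc)), cc, nc)
        } else {
          rr <- r0:min(r0 + len - 1L, nr - 1L)
          seg <- rc_state(rr, rep(c0, length(rr)), nc)
        }
        seg <- setdiff(seg, goal_state)
        over <- sum(!pres) + length(seg) - n_rm
        if (over > 0L) seg <- seg[seq_len(max(length(seg) - over, 0L))]
        pres[seg] <- FALSE
      }
      maze <- maze_config(matrix(pres, nr, nc, byrow = TRUE), goal_state,
                          id = sprintf("synthetic-%02d", k))
      d <- distance_map(maze, goal_state)
      cand <- which(!is.na(d) & d > 0L & (if (edge_starts) on_edge else TRUE))
      if (length(cand) < n_starts) next
      tort <- vapply(cand, function(s) tortuosity(maze, s, goal_state),
                     numeric(1))
      keep <- tort >= min_tortuosity
      cand <- cand[keep]
      tort <- tort[keep]
      if (length(cand) < n_starts) next
      if (max(tort) < min_max_tortuosity) next
      # one start per tortuosity quantile bin, then sort: graded difficulty
      ord <- order(tort)
      bins <- split(cand[ord], cut(seq_along(ord), n_starts, labels = FALSE))
      ss <- vapply(bins, function(b) b[sample.int(length(b), 1L)], integer(1))
      ss <- ss[order(vapply(ss, function(s) tortuosity(maze, s, goal_state),
                            numeric(1)))]
      configs[[k]] <- maze
      starts[[k]] <- unname(ss)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not generate configuration ", k, " within ", max_retries,
           " retries; relax the density or tortuosity constraints")
    }
  }
  make_schedule(configs, starts)
}

#' Generate a surrogate subject from a ground-truth agent
#'
#' Initializes an agent of the ground-truth kind on the open maze and rolls
#' out every scheduled trial with either a softmax(beta) policy or the
#' decaying epsilon-greedy trial schedule, plus lapse noise, learning
#' continuously across trials and configurations (the same mechanics as the
#' simulation module). The ground truth is attached as an attribute so
#' recovery tests can compare fitted against true parameters.
#'
#' @param gt A [ground_truth()].
#' @param schedule An `experiment_schedule`.
#' @param step_cap Maximum transitions per trial (default 45).
#' @param policy `"softmax"` (uses `gt$params$beta`) or `"egreedy"` (uses the
#'   decaying epsilon schedule of [epsilon_for_trial()]).
#' @param eps_start,eps_end Epsilon endpoints for `policy = "egreedy"`.
#' @param subject_id Identifier (defaults to a kind-derived label).
#' @param species Species label (default "synthetic").
#' @return A `subject_data` with attribute `ground_truth`.
#' @export
generate_subject <- function(gt, schedule, step_cap = 45L,
                             policy = c("softmax", "egreedy"),
                             eps_start = 0.1, eps_end = 0.01,
                             subject_id = NULL, species = "synthetic") {
  policy <- match.arg(policy)
  if (is.null(subject_id)) {
    subject_id <- sprintf("synth-%s-%d", gt$kind, gt$seed)
  }
  maze1 <- schedule$configs[[1L]]
  open <- open_maze(maze1$nr, maze1$nc, maze1$goal)
  agent <- initialize_agent(gt$params, open)
  set.seed(child_seed(gt$seed, "subject", gt$kind))
  trials <- vector("list", length(schedule$configs))
  for (k in seq_along(schedule$configs)) {
    maze <- schedule$configs[[k]]
    trials_k <- vector("list", schedule$trials_per_config[k])
    for (t in seq_len(schedule$trials_per_config[k])) {
      res <- if (policy == "softmax") {
        run_trial(agent, maze, schedule$starts[[k]][t],
                  step_cap = step_cap, policy = "softmax",
                  beta = gt$params$beta, lapse = gt$lapse)
      } else {
        run_trial(agent, maze, schedule$starts[[k]][t],
                  step_cap = step_cap, policy = "egreedy",
                  epsilon = epsilon_for_trial(t, schedule$trials_per_config[k],
                                              eps_start, eps_end),
                  lapse = gt$lapse)
      }
      agent <- res$agent
      tr <- res$trajectory
      tr$subject_id <- subject_id
      tr$config_index <- k
      tr$trial_index <- t
      trials_k[[t]] <- tr
    }
    trials[[k]] <- trials_k
  }
  out <- subject_data(subject_id, species = species, trials = trials,
                      schedule = schedule)
  attr(out, "ground_truth") <- gt
  out
}

#' Generate a cohort of surrogate subjects across agent kinds
#'
#' Samples each subject's parameters uniformly from the stated ranges and
#' rolls the subject out on the schedule; deterministic given `seed`. Each
#' subject records its ground truth.
#'
#' @param n_per_kind Subjects per generating kind (default 6).
#' @param schedule An `experiment_schedule`.
#' @param kinds Generating kinds (default all three).
#' @param alpha_range,gamma_range Uniform sampling ranges for the learning
#'   rate and discount.
#' @param beta,lapse Held fixed across the cohort. The default `beta = 5`
#'   produces goal-directed but noisy surrogate subjects whose per-config
#'   goal-reaching rates (~0.6-0.8) match the range real subjects show on
#'   this task; `beta = 1` yields near-random walkers.
#' @param step_cap Maximum transitions per trial.
#' @param seed Master seed.
#' @return Named list of `subject_data` (empty when `n_per_kind = 0`).
#' @export
make_cohort <- function(n_per_kind = 6L, schedule, kinds = c("MF", "MB", "SR"),
                        alpha_range = c(0.05, 0.3), gamma_range = c(0.6, 0.95),
                        beta = 5, lapse = 0.05, step_cap = 45L, seed = 1L) {
  if (diff(alpha_range) < 0 || diff(gamma_range) < 0) stop("empty parameter range")
  subjects <- list()
  for (kind in kinds) {
    for (i in seq_len(n_per_kind)) {
      sub_seed <- child_seed(seed, "cohort", kind, i)
      set.seed(sub_seed)
      gt <- ground_truth(kind,
                         alpha = stats::runif(1, alpha_range[1L], alpha_range[2L]),
                         gamma = stats::runif(1, gamma_range[1L], gamma_range[2L]),
                         beta = beta, lapse = lapse, seed = sub_seed)
      sid <- sprintf("synth-%s-%02d", kind, i)
      subjects[[sid]] <- generate_subject(gt, schedule, step_cap = step_cap,
                                          subject_id = sid)
    }
  }
  subjects
}
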