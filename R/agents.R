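# Tabular reinforcement-learning agents: model-free Q(lambda), successor
# representation with TD(lambda), and model-based planning over a learned
# binary module map.

#' Agent parameters
#'
#' @param kind One of `"MF"`, `"MB"`, `"SR"`.
#' @param alpha Learning rate in \[0, 1\]. Ignored by the MB agent, whose
#'   model update is binary and deterministic.
#' @param gamma Discount factor in \[0, 1).
#' @param lambda Eligibility-trace decay, fixed at 0.5 by convention.
#' @param beta Softmax inverse temperature (> 0), fixed at 1 by default; used
#'   only by the likelihood machinery and softmax rollouts.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(kind = c("MF", "MB", "SR"), alpha = 0.1, gamma = 0.9,
                         lambda = 0.5, beta = 1) {
  kind <- match.arg(kind)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (beta <= 0) stop("beta must be positive")
  structure(list(kind = kind, alpha = alpha, gamma = gamma, lambda = lambda,
                 beta = beta), class = "agent_params")
}

#' Closed-form successor representation of a policy
#'
#' For a row-stochastic (or sub-stochastic) one-step transition matrix
#' `T_pi`, the successor matrix is the discounted sum of future transitions,
#' `M = I + gamma T + gamma^2 T^2 + ... = (I - gamma T)^{-1}`. With the goal
#' row of `T_pi` zeroed (episodes terminate on goal entry) the goal row of `M`
#' is the one-hot of the goal and `M[s, goal] = gamma^d(s)` under an optimal
#' policy.
#'
#' @param T_pi Square numeric transition matrix.
#' @param gamma Discount factor in \[0, 1).
#' @return The successor matrix `M`.
#' @export
sr_closed_form <- function(T_pi, gamma) {
  n <- nrow(T_pi)
  solve(diag(n) - gamma * T_pi)
}

#' Initialize an agent with the optimal policy on the open maze
#'
#' Emulates the training phase: before any barrier configuration is seen, each
#' agent is endowed with representations under which a greedy rollout from any
#' start on the open maze reaches the goal in exactly shortest-path steps.
#'
#' * MF: `Q(s, a) = gamma^d(s')` where `s'` is the successor of `(s, a)` and
#'   `d` its open-maze shortest-path distance to the goal (`d = 0` gives
#'   `Q = 1`); actions leaving the grid get value 0.
#' * SR: `M` is the closed-form successor matrix of the open-maze optimal
#'   policy, ties among optimal actions averaged, goal absorbing, so
#'   `V(s) = M[s, goal] = gamma^d(s)`.
#' * MB: the binary module map `chi` is all ones.
#'
#' @param params An `agent_params`.
#' @param open_maze A fully present `maze_config` carrying the goal.
#' @return Object of class `rl_agent`. Fields by kind: `Q` and `e_sa`
#'   (`n x 4` matrices) for MF; `M` (`n x n`) and `e_s` (length `n`) for SR;
#'   `chi` (logical length `n`) plus a planning cache for MB.
#' @export
initialize_agent <- function(params, open_maze) {
  if (!all(open_maze$present)) {
    stop("initialization requires the fully open maze")
  }
  n <- length(open_maze$present)
  d <- distance_map(open_maze, open_maze$goal)
  agent <- structure(
    list(kind = params$kind, params = params, nr = open_maze$nr,
         nc = open_maze$nc, n = n, Q = NULL, e_sa = NULL, M = NULL,
         e_s = NULL, chi = NULL, chi_version = 0L, cache = NULL),
    class = "rl_agent"
  )
  if (params$kind == "MF") {
    Q <- matrix(0, n, 4L)
    nbr <- open_maze$nbr
    for (a in 1:4) {
      ok <- !is.na(nbr[a, ])
      Q[ok, a] <- params$gamma^d[nbr[a, ok]]
    }
    agent$Q <- Q
    agent$e_sa <- matrix(0, n, 4L)
  } else if (params$kind == "SR") {
    T_pi <- matrix(0, n, n)
    for (s in seq_len(n)) {
      if (s == open_maze$goal) next
      nb <- open_maze$nbr[, s]
      nb <- nb[!is.na(nb)]
      opt <- nb[d[nb] == d[s] - 1L]
      T_pi[s, opt] <- 1 / length(opt)
    }
    agent$M <- sr_closed_form(T_pi, params$gamma)
    agent$e_s <- numeric(n)
  } else {
    agent$chi <- rep(TRUE, n)
    agent$cache <- new.env(parent = emptyenv())
  }
  agent
}

#' Deep-copy an agent
#'
#' Agents are plain values except for the MB planning cache, which lives in an
#' environment; cloning gives the copy its own cache so simulation replicates
#' are fully independent.
#'
#' @param agent An `rl_agent`.
#' @return An independent copy.
#' @export
clone_agent <- function(agent) {
  if (!is.null(agent$cache)) agent$cache <- new.env(parent = emptyenv())
  agent
}

#' Reset eligibility traces
#'
#' Traces are zeroed at the beginning of each trial; learned structures
#' (`Q`, `M`, `chi`) are untouched. Idempotent.
#'
#' @param agent An `rl_agent`.
#' @return The agent with zero traces.
#' @export
reset_eligibility <- function(agent) {
  if (!is.null(agent$e_sa)) agent$e_sa[] <- 0
  if (!is.null(agent$e_s)) agent$e_s[] <- 0
  agent
}

# Shortest-path distances from every state to `goal` through the MB agent's
# internal model chi, memoised on (chi_version, goal).
mb_distances <- function(agent, goal) {
  key <- paste0(agent$chi_version, ":", goal)
  cache <- agent$cache
  if (identical(cache$key, key)) return(cache$d)
  d <- bfs_distances(agent$chi, lattice_neighbors(agent$nr, agent$nc), goal)
  cache$key <- key
  cache$d <- d
  d
}

#' Values of candidate next states
#'
#' The action set is the set of locally available transitions (adjacent
#' present modules). MF returns cached `Q(s, a)`; SR returns `M(s', goal)`
#' (its value estimate of `s'` under unit goal reward); MB plans through its
#' internal model and returns `gamma^d_chi(s')`, the discounted planned path
#' length from each candidate to the goal (0 when its model disconnects the
#' candidate from the goal). All values lie in \[0, 1\] under the
#' initialization conventions.
#'
#' @param agent An `rl_agent`.
#' @param state Current state.
#' @param candidates Integer vector of available next states (adjacent present
#'   modules); must be non-empty.
#' @param maze The true `maze_config` (supplies the goal).
#' @return Numeric vector of values, one per candidate.
#' @export
action_values <- function(agent, state, candidates, maze) {
  if (!length(candidates)) stop("empty candidate set: dead state")
  switch(agent$kind,
    MF = agent$Q[cbind(state, action_between(state, candidates, agent$nc))],
    SR = agent$M[candidates, maze$goal],
    MB = {
      d <- mb_distances(agent, maze$goal)[candidates]
      v <- agent$params$gamma^d
      v[is.na(v)] <- 0
      v
    }
  )
}

#' Model-free TD(lambda) update
#'
#' Applied after each transition, in this exact order: decay the whole trace
#' `e <- lambda * gamma * e`, increment `e(s_t, a_t)` by 1, then update every
#' state-action value proportionally to its trace,
#' `Q <- Q + alpha * (r + gamma * max_a Q(s_{t+1}, a) - Q(s_t, a_t)) * e`.
#' At a terminal transition (goal entry) the bootstrap term is 0.
#'
#' @param agent An MF `rl_agent`.
#' @param from,action,to The transition taken (`action` in 1:4).
#' @param reward Reward received (1 on goal entry, else 0).
#' @param terminal Whether `to` is the goal.
#' @param next_actions Integer vector of actions available at `to` in the true
#'   maze, over which the bootstrap max is taken (unused when terminal).
#' @return The updated agent.
#' @export
update_model_free <- function(agent, from, action, to, reward, terminal,
                              next_actions = 1:4) {
  p <- agent$params
  e <- agent$e_sa * (p$lambda * p$gamma)
  e[e < 1e-12] <- 0
  e[from, action] <- e[from, action] + 1
  boot <- if (terminal) 0 else max(agent$Q[to, next_actions])
  delta <- reward + p$gamma * boot - agent$Q[from, action]
  nz <- which(e != 0)
  if (length(nz)) agent$Q[nz] <- agent$Q[nz] + p$alpha * delta * e[nz]
  agent$e_sa <- e
  agent
}

#' Successor-representation TD(lambda) update
#'
#' Applied after each transition, in this exact order: decay the state trace
#' `e <- lambda * gamma * e`, increment `e(s_t)` by 1, then update every
#' state's row of `M` proportionally to its trace via the outer product
#' `M <- M + alpha * e %o% (1_{s_t} + gamma * M(s_{t+1}, ) - M(s_t, ))`.
#' When `s_{t+1}` is the goal its row is the fixed one-hot of the goal
#' (episodes terminate there), which keeps `V(s) = M(s, goal)`
#' self-consistent. The reward vector is never learned: `R(s) = 1` iff `s` is
#' the goal.
#'
#' @param agent An SR `rl_agent`.
#' @param from,to The state transition taken.
#' @param goal The goal state of the current maze.
#' @return The updated agent.
#' @export
update_successor <- function(agent, from, to, goal) {
  p <- agent$params
  e <- agent$e_s * (p$lambda * p$gamma)
  e[e < 1e-12] <- 0
  e[from] <- e[from] + 1
  if (to == goal) {
    delta <- -agent$M[from, ]
    delta[goal] <- delta[goal] + p$gamma
  } else {
    delta <- p$gamma * agent$M[to, ] - agent$M[from, ]
  }
  delta[from] <- delta[from] + 1
  nz <- which(e != 0)
  if (length(nz)) {
    agent$M[nz, ] <- agent$M[nz, ] + p$alpha * e[nz] %o% delta
  }
  agent$e_s <- e
  agent
}

#' Update the model-based agent's internal module map
#'
#' The MB agent carries a binary per-module presence model `chi`. On each
#' observation it overwrites exactly the observed entries; everything else
#' retains its previous value, so stale beliefs persist across configuration
#' changes by design.
#'
#' @param agent An MB `rl_agent`.
#' @param state The state at which the observation is made.
#' @param neighbors Integer vector of observed modules; each must be a lattice
#'   neighbour of `state`.
#' @param present Logical vector parallel to `neighbors`.
#' @return The updated agent.
#' @export
update_model <- function(agent, state, neighbors, present) {
  lat <- lattice_neighbors(agent$nr, agent$nc)[, state]
  if (!all(neighbors %in% lat[!is.na(lat)])) {
    stop("observation of a module that is not adjacent to the current state")
  }
  present <- as.logical(present)
  if (any(agent$chi[neighbors] != present)) {
    agent$chi[neighbors] <- present
    agent$chi_version <- agent$chi_version + 1L
  }
  agent
}

#' Observe the true adjacency at a state
#'
#' Convenience wrapper around [update_model()]: the agent standing on `state`
#' sees, through the fog, which of its lattice neighbours are present in the
#' true maze. A no-op for MF and SR agents.
#'
#' @param agent An `rl_agent`.
#' @param state The occupied state.
#' @param maze The true `maze_config`.
#' @return The (possibly updated) agent.
#' @export
observe_state <- function(agent, state, maze) {
  if (agent$kind != "MB") return(agent)
  lat <- lattice_neighbors(agent$nr, agent$nc)[, state]
  lat <- lat[!is.na(lat)]
  update_model(agent, state, lat, maze$present[lat])
}

#' Apply an agent's learning update for one observed transition
#'
#' Dispatches on kind: MF applies the Q(lambda) update (with the bootstrap
#' taken over actions available at the new state in the true maze), SR the
#' successor update, and MB observes the adjacency at the new state.
#'
#' @param agent An `rl_agent`.
#' @param maze The true `maze_config` the transition happened on.
#' @param from,to The transition (orthogonally adjacent present states).
#' @return The updated agent.
#' @export
agent_step_update <- function(agent, maze, from, to) {
  terminal <- to == maze$goal
  switch(agent$kind,
    MF = {
      a <- action_between(from, to, agent$nc)
      nxt <- if (terminal) integer(0) else which(!is.na(maze$nbr[, to]))
      update_model_free(agent, from, a, to, as.numeric(terminal), terminal, nxt)
    },
    SR = update_successor(agent, from, to, maze$goal),
    MB = observe_state(agent, to, maze)
  )
}

#' Choice probabilities over candidate next states
#'
#' Two rules, both tie-aware (ties never break by index):
#' * `"egreedy"`: mass `1 - epsilon` split uniformly over the argmax
#'   candidates, plus `epsilon` split uniformly over all candidates (the
#'   random action may coincide with the greedy one).
#' * `"softmax"`: `p propto exp(beta * value)`.
#'
#' @param values Numeric candidate values (length >= 1).
#' @param policy `"softmax"` or `"egreedy"`.
#' @param beta Inverse temperature (softmax).
#' @param epsilon Exploration rate (egreedy).
#' @return Numeric probability vector summing to 1.
#' @export
choice_distribution <- function(values, policy = c("softmax", "egreedy"),
                                beta = 1, epsilon = 0.1) {
  if (!length(values)) stop("empty candidate set")
  policy <- match.arg(policy)
  k <- length(values)
  if (policy == "softmax") {
    z <- beta * values
    z <- exp(z - max(z))
    z / sum(z)
  } else {
    is_max <- values >= max(values) - 1e-12
    (1 - epsilon) * is_max / sum(is_max) + epsilon / k
  }
}
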