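# Trajectory-level comparison statistics: occupancy, optimality, goal rates,
# diffusivity features, Mahalanobis dissimilarity, minimum path-distance
# similarity, difficulty rankings.

# Accept a trajectory, a list of trajectories, or a bare integer vector.
as_state_lists <- function(trajectories) {
  if (inherits(trajectories, "trajectory")) return(list(trajectories$states))
  if (is.numeric(trajectories)) return(list(as.integer(trajectories)))
  lapply(trajectories, function(tr) {
    if (inherits(tr, "trajectory")) tr$states else as.integer(tr)
  })
}

#' Occupancy map over one or more trajectories
#'
#' The proportion of time spent in each state, counting one unit per
#' step-sample (revisits accumulate).
#'
#' @param trajectories A `trajectory`, list of trajectories, or integer state
#'   vector(s).
#' @param n_states Number of states in the grid (default 100).
#' @return Numeric vector of length `n_states`, non-negative, summing to 1.
#' @export
occupancy_map <- function(trajectories, n_states = 100L) {
  sl <- as_state_lists(trajectories)
  if (!length(sl)) stop("occupancy_map needs at least one trajectory")
  counts <- tabulate(unlist(sl, use.names = FALSE), nbins = n_states)
  counts / sum(counts)
}

#' Pearson correlation between two occupancy maps
#'
#' @param map_a,map_b Occupancy vectors on the same grid.
#' @return Pearson correlation over the per-state proportions.
#' @export
occupancy_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stop("maps cover different grids")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0) {
    stop("occupancy correlation undefined for a zero-variance map")
  }
  stats::cor(map_a, map_b)
}

#' Deviation from the optimal path, in extra module visitations
#'
#' Number of module visitations in the trajectory minus the visitation count
#' of an optimal path from its start to the goal. Defined only for trials
#' that reached the goal; for a non-reached trial `NA` is returned with
#' `reached = FALSE` so callers can report failures separately.
#'
#' @param traj A `trajectory` (or state vector).
#' @param maze The `maze_config` of the trial.
#' @return List with `extra` (integer or `NA`) and `reached` (logical).
#' @export
deviation_from_optimal <- function(traj, maze) {
  states <- as_state_lists(traj)[[1L]]
  opt <- shortest_path(maze, states[1L], maze$goal)
  if (is.na(opt$length)) stop("goal unreachable from the trajectory start")
  reached <- states[length(states)] == maze$goal
  if (!reached) return(list(extra = NA_integer_, reached = FALSE))
  list(extra = length(states) - (opt$length + 1L), reached = TRUE)
}

#' Proportion of trials on which the goal was reached
#'
#' @param trajectories List of `trajectory` objects (with `goal_reached`
#'   flags) or a logical vector of flags.
#' @return Mean of the goal-reached flags.
#' @export
goal_rate <- function(trajectories) {
  if (is.logical(trajectories)) flags <- trajectories
  else flags <- vapply(trajectories, `[[`, logical(1), "goal_reached")
  if (!length(flags)) stop("goal_rate of an empty group is undefined")
  mean(flags)
}

#' Diffusivity features of a trajectory
#'
#' Treats the discretised route like a particle track. The linear diffusivity
#' follows the 2-D mean-squared-displacement convention,
#' `D_lin = |r_end - r_start|^2 / (4 n_steps)` in module^2 per step. The
#' heading of each step is its displacement angle in the maze frame (x along
#' columns, y along decreasing rows, so east = 0, north = pi/2); `phi` is the
#' circular mean of the step headings and the features are `sin(phi)` and
#' `cos(phi)`. When the headings cancel exactly (zero resultant) the angular
#' features are undefined and returned as `NA`. Zero-length steps cannot
#' occur after discretisation (consecutive duplicates are collapsed).
#'
#' @param traj A `trajectory` or state vector with at least one step.
#' @param nc Grid columns used to decode states (default 10).
#' @return Named numeric vector `c(D_lin, sin_phi, cos_phi)`.
#' @export
diffusivity_features <- function(traj, nc = 10L) {
  states <- as_state_lists(traj)[[1L]]
  if (length(states) < 2L) stop("diffusivity undefined for a zero-step trajectory")
  rc <- state_rc(states, nc)
  n_steps <- length(states) - 1L
  disp <- rc[length(states), ] - rc[1L, ]
  d_lin <- sum(disp^2) / (4 * n_steps)
  dx <- diff(rc[, "col"])
  dy <- -diff(rc[, "row"])
  sx <- mean(dx / sqrt(dx^2 + dy^2))
  sy <- mean(dy / sqrt(dx^2 + dy^2))
  r <- sqrt(sx^2 + sy^2)
  if (r < 1e-12) {
    c(D_lin = d_lin, sin_phi = NA_real_, cos_phi = NA_real_)
  } else {
    c(D_lin = d_lin, sin_phi = sy / r, cos_phi = sx / r)
  }
}

#' Per-configuration diffusivity features
#'
#' Mean of the per-trial feature vectors over a configuration's trials;
#' trials with undefined angular features are dropped from the angular means.
#'
#' @param trajectories List of `trajectory` objects for one configuration.
#' @param nc Grid columns.
#' @return Named numeric vector `c(D_lin, sin_phi, cos_phi)`.
#' @export
config_diffusivity <- function(trajectories, nc = 10L) {
  sl <- as_state_lists(trajectories)
  keep <- lengths(sl) >= 2L
  feats <- t(vapply(sl[keep], diffusivity_features, numeric(3), nc = nc))
  colMeans(feats, na.rm = TRUE)
}

#' Mahalanobis dissimilarity of a feature point from an agent cluster
#'
#' `sqrt((x - mu)' Sigma^{-1} (x - mu))` with `mu` and `Sigma` estimated from
#' the cluster of agent-replicate feature vectors. When `Sigma` is
#' near-singular, `1e-6` is added to its diagonal (with a message).
#'
#' @param x Numeric feature vector.
#' @param cluster Numeric matrix, one replicate per row; must have more rows
#'   than columns.
#' @return The Mahalanobis distance (not squared).
#' @export
mahalanobis_dissimilarity <- function(x, cluster) {
  cluster <- as.matrix(cluster)
  if (nrow(cluster) <= ncol(cluster)) {
    stop("cluster must contain more replicates than feature dimensions")
  }
  mu <- colMeans(cluster)
  sigma <- stats::cov(cluster)
  d2 <- tryCatch(
    stats::mahalanobis(x, mu, sigma),
    error = function(e) {
      message("near-singular covariance: regularizing diagonal by 1e-6")
      stats::mahalanobis(x, mu, sigma + diag(1e-6, ncol(cluster)))
    })
  if (is.na(d2) || d2 < 0) stop("Mahalanobis distance could not be computed")
  sqrt(d2)
}

#' Minimum path-distance similarity between a reference trajectory and
#' agent replicates
#'
#' For each replicate, at every time point along the reference trajectory the
#' shortest-path distance on the maze to the nearest state visited by that
#' replicate is found; averaging along the reference and then over replicates
#' gives the similarity (0 = the replicates cover the reference everywhere).
#' A reference state disconnected from all of a replicate's states is scored
#' as maze diameter + 1 (occurrences counted in the `capped` attribute).
#'
#' @param reference A `trajectory` (or state vector) on `maze`.
#' @param agent_trajs List of trial-matched agent trajectories (one per
#'   replicate) on the same configuration.
#' @param maze The `maze_config`.
#' @return Mean distance (numeric); attribute `per_replicate` holds the
#'   replicate means and `capped` the number of capped distances.
#' @export
min_path_distance_similarity <- function(reference, agent_trajs, maze) {
  ref <- as_state_lists(reference)[[1L]]
  reps <- as_state_lists(agent_trajs)
  lat <- lattice_neighbors(maze$nr, maze$nc)
  uref <- unique(ref)
  dmaps <- lapply(uref, function(s) bfs_distances(maze$present, lat, s))
  names(dmaps) <- uref
  cap <- maze_diameter(maze) + 1L
  capped <- 0L
  per_rep <- vapply(reps, function(rs) {
    visited <- unique(rs)
    mean(vapply(ref, function(s) {
      d <- dmaps[[as.character(s)]][visited]
      d <- d[!is.na(d)]
      if (!length(d)) {
        capped <<- capped + 1L
        return(as.numeric(cap))
      }
      min(d)
    }, numeric(1)))
  }, numeric(1))
  out <- mean(per_rep)
  attr(out, "per_replicate") <- per_rep
  attr(out, "capped") <- capped
  out
}

#' Rank correlation between subject and agent difficulty orderings
#'
#' Configurations are ranked by goal-reaching performance (average ranks for
#' ties) and compared with the Spearman correlation; the Fisher transform
#' `z = atanh(rho)` is returned for downstream paired t-tests. Constant rates
#' have undefined ranks and yield `NA` with a warning.
#'
#' @param subject_rates Numeric per-configuration goal rates for the subject.
#' @param agent_rates Per-configuration goal rates for one agent kind, or a
#'   named list of such vectors (one per kind).
#' @return Data frame with columns `kind`, `rho`, `z`.
#' @export
difficulty_rankings <- function(subject_rates, agent_rates) {
  if (!is.list(agent_rates)) agent_rates <- list(agent = agent_rates)
  if (length(subject_rates) < 3L) stop("need at least 3 configurations")
  rows <- lapply(names(agent_rates), function(kind) {
    ar <- agent_rates[[kind]]
    if (length(ar) != length(subject_rates)) stop("rate vectors differ in length")
    if (stats::sd(subject_rates) == 0 || stats::sd(ar) == 0) {
      warning("constant goal rates: difficulty ranking undefined for ", kind)
      return(data.frame(kind = kind, rho = NA_real_, z = NA_real_))
    }
    rho <- stats::cor(subject_rates, ar, method = "spearman")
    data.frame(kind = kind, rho = rho, z = atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12)))
  })
  do.call(rbind, rows)
}

#' Paired t statistic
#'
#' Standard paired t with `dof = n - 1`. A zero-variance non-zero difference
#' is flagged as infinite (with sign); identical samples give `t = 0`.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return List with `t`, `dof`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("samples must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t <- mean(d) / (s / sqrt(n))
  }
  list(t = t, dof = n - 1L)
}
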