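# Forced-trajectory likelihoods, maximum-likelihood fitting, model comparison.

# Precompute everything about a subject's walk that does not depend on agent
# parameters: per-trial step arrays, candidate sets and the index of the
# observed candidate. Validates adjacency as it goes.
build_walk_plan <- function(subject, schedule) {
  if (length(subject$trials) != length(schedule$configs)) {
    stop("subject/schedule mismatch: ", length(subject$trials), " vs ",
         length(schedule$configs), " configurations")
  }
  plan <- vector("list", length(schedule$configs))
  for (k in seq_along(schedule$configs)) {
    maze <- schedule$configs[[k]]
    trials <- subject$trials[[k]]
    if (length(trials) != schedule$trials_per_config[k]) {
      stop("configuration ", k, ": subject has ", length(trials),
           " trials, schedule expects ", schedule$trials_per_config[k])
    }
    ptrials <- vector("list", length(trials))
    for (t in seq_along(trials)) {
      st <- trials[[t]]$states
      validate_trajectory(st, maze)
      n_steps <- length(st) - 1L
      if (n_steps > 0L) {
        from <- st[-length(st)]
        to <- st[-1L]
        cand <- vector("list", n_steps)
        cand_act <- vector("list", n_steps)
        next_act <- vector("list", n_steps)
        obs_idx <- integer(n_steps)
        for (i in seq_len(n_steps)) {
          col <- maze$nbr[, from[i]]
          keep <- which(!is.na(col))
          cs <- col[keep]
          cand[[i]] <- cs
          cand_act[[i]] <- keep
          obs_idx[i] <- match(to[i], cs)
          next_act[[i]] <- which(!is.na(maze$nbr[, to[i]]))
        }
        ptrials[[t]] <- list(states = st, from = from, to = to, cand = cand,
                             cand_act = cand_act, next_act = next_act,
                             obs_idx = obs_idx, ncand = lengths(cand),
                             n_steps = n_steps,
                             chance = -sum(log(lengths(cand))),
                             terminal = to == maze$goal)
      } else {
        ptrials[[t]] <- list(states = st, n_steps = 0L, chance = 0)
      }
    }
    plan[[k]] <- list(maze = maze, trials = ptrials)
  }
  plan
}

#' Forced-walk log-likelihood of a subject under an agent
#'
#' Runs a single sequential pass over the whole experiment in trial order:
#' the agent is initialized with the optimal policy on the open maze, then,
#' trial by trial, its eligibility trace is reset, and for each observed step
#' the softmax choice distribution over the truly available transitions is
#' evaluated from the agent's current values, the log-probability of the
#' observed next state is accumulated, and the agent's learning update is
#' applied on the observed transition (the MB agent additionally observes the
#' adjacency at each state it enters, including the trial start). Learned
#' representations carry across trials and configurations; nothing from future
#' trials influences earlier likelihoods.
#'
#' A probability floor of `1e-12` per step keeps the log finite; applications
#' of the floor are counted in the `floored` attribute.
#'
#' @param params An `agent_params` (its `kind` selects the agent).
#' @param subject A `subject_data`.
#' @param schedule The `experiment_schedule` the subject ran.
#' @param open A fully present `maze_config` for initialization; defaults to
#'   an open maze of the schedule's geometry and goal.
#' @return Data frame of per-trial likelihoods with columns `config`, `trial`,
#'   `loglik`, `n_steps`, `chance_loglik` (the uniform-random-walk
#'   log-likelihood of the same trial); attribute `cand_counts` holds the
#'   per-step candidate counts per trial.
#' @export
forced_walk_loglik <- function(params, subject, schedule, open = NULL) {
  plan <- build_walk_plan(subject, schedule)
  walk_loglik(params, plan, open = open)
}

# Core evaluator over a prebuilt plan. Tight per-kind loops over the
# precomputed step arrays; equivalence with stepping the public agent API is
# checked by the test suite.
walk_loglik <- function(params, plan, open = NULL) {
  maze1 <- plan[[1L]]$maze
  if (is.null(open)) open <- open_maze(maze1$nr, maze1$nc, maze1$goal)
  agent <- initialize_agent(params, open)
  core <- switch(params$kind, MF = walk_core_mf, SR = walk_core_sr,
                 MB = walk_core_mb)
  res <- core(agent, plan, params)
  out <- data.frame(
    config = rep(seq_along(plan),
                 vapply(plan, function(cfg) length(cfg$trials), integer(1))),
    trial = unlist(lapply(plan, function(cfg) seq_along(cfg$trials))),
    loglik = res$ll,
    n_steps = unlist(lapply(plan, function(cfg)
      vapply(cfg$trials, `[[`, integer(1), "n_steps"))),
    chance_loglik = unlist(lapply(plan, function(cfg)
      vapply(cfg$trials, `[[`, numeric(1), "chance")))
  )
  attr(out, "cand_counts") <- unlist(lapply(plan, function(cfg)
    lapply(cfg$trials, function(tr)
      if (tr$n_steps > 0L) tr$ncand else integer(0))), recursive = FALSE)
  attr(out, "floored") <- res$floored
  attr(out, "params") <- params
  out
}

# log softmax probability of the observed candidate, with the 1e-12 floor
LOG_FLOOR <- log(1e-12)
step_logp <- function(v, beta, obs) {
  z <- beta * v
  z <- exp(z - max(z))
  p <- z[obs] / sum(z)
  if (p < 1e-12) LOG_FLOOR else log(p)
}

walk_core_sr <- function(agent, plan, params) {
  M <- agent$M
  n <- agent$n
  alpha <- params$alpha
  gamma <- params$gamma
  lg <- params$lambda * gamma
  beta <- params$beta
  ll_out <- numeric(0)
  floored <- 0L
  for (k in seq_along(plan)) {
    maze <- plan[[k]]$maze
    goal <- maze$goal
    lls <- numeric(length(plan[[k]]$trials))
    for (t in seq_along(plan[[k]]$trials)) {
      tr <- plan[[k]]$trials[[t]]
      if (tr$n_steps == 0L) next
      e <- numeric(n)
      ll <- 0
      for (i in seq_len(tr$n_steps)) {
        v <- M[tr$cand[[i]], goal]
        lp <- step_logp(v, beta, tr$obs_idx[i])
        if (lp == LOG_FLOOR) floored <- floored + 1L
        ll <- ll + lp
        from <- tr$from[i]
        e <- e * lg
        e[e < 1e-12] <- 0
        e[from] <- e[from] + 1
        if (tr$terminal[i]) {
          delta <- -M[from, ]
          delta[goal] <- delta[goal] + gamma
        } else {
          delta <- gamma * M[tr$to[i], ] - M[from, ]
        }
        delta[from] <- delta[from] + 1
        nz <- which(e != 0)
        M[nz, ] <- M[nz, ] + alpha * e[nz] %o% delta
      }
      lls[t] <- ll
    }
    ll_out <- c(ll_out, lls)
  }
  list(ll = ll_out, floored = floored)
}

walk_core_mf <- function(agent, plan, params) {
  Q <- agent$Q
  n <- agent$n
  alpha <- params$alpha
  gamma <- params$gamma
  lg <- params$lambda * gamma
  beta <- params$beta
  ll_out <- numeric(0)
  floored <- 0L
  for (k in seq_along(plan)) {
    lls <- numeric(length(plan[[k]]$trials))
    for (t in seq_along(plan[[k]]$trials)) {
      tr <- plan[[k]]$trials[[t]]
      if (tr$n_steps == 0L) next
      e <- matrix(0, n, 4L)
      ll <- 0
      for (i in seq_len(tr$n_steps)) {
        from <- tr$from[i]
        v <- Q[(tr$cand_act[[i]] - 1L) * n + from]
        lp <- step_logp(v, beta, tr$obs_idx[i])
        if (lp == LOG_FLOOR) floored <- floored + 1L
        ll <- ll + lp
        a <- tr$cand_act[[i]][tr$obs_idx[i]]
        e <- e * lg
        e[e < 1e-12] <- 0
        e[from, a] <- e[from, a] + 1
        if (tr$terminal[i]) {
          delta <- 1 - Q[from, a]
        } else {
          delta <- gamma * max(Q[(tr$next_act[[i]] - 1L) * n + tr$to[i]]) -
            Q[from, a]
        }
        nz <- which(e != 0)
        Q[nz] <- Q[nz] + alpha * delta * e[nz]
      }
      lls[t] <- ll
    }
    ll_out <- c(ll_out, lls)
  }
  list(ll = ll_out, floored = floored)
}

walk_core_mb <- function(agent, plan, params) {
  chi <- agent$chi
  nr <- agent$nr
  nc <- agent$nc
  lat <- lattice_neighbors(nr, nc)
  gamma <- params$gamma
  beta <- params$beta
  ll_out <- numeric(0)
  floored <- 0L
  dist <- NULL      # distance-to-goal map through chi; NULL = stale
  goal_cached <- NA_integer_
  for (k in seq_along(plan)) {
    maze <- plan[[k]]$maze
    goal <- maze$goal
    if (!identical(goal, goal_cached)) {
      dist <- NULL
      goal_cached <- goal
    }
    observe <- function(s) {
      col <- lat[, s]
      idx <- col[!is.na(col)]
      newp <- maze$present[idx]
      if (any(chi[idx] != newp)) {
        chi[idx] <<- newp
        dist <<- NULL
      }
    }
    lls <- numeric(length(plan[[k]]$trials))
    for (t in seq_along(plan[[k]]$trials)) {
      tr <- plan[[k]]$trials[[t]]
      if (tr$n_steps == 0L) next
      observe(tr$states[1L])
      ll <- 0
      for (i in seq_len(tr$n_steps)) {
        if (is.null(dist)) dist <- bfs_distances(chi, lat, goal)
        v <- gamma^dist[tr$cand[[i]]]
        v[is.na(v)] <- 0
        lp <- step_logp(v, beta, tr$obs_idx[i])
        if (lp == LOG_FLOOR) floored <- floored + 1L
        ll <- ll + lp
        observe(tr$to[i])
      }
      lls[t] <- ll
    }
    ll_out <- c(ll_out, lls)
  }
  list(ll = ll_out, floored = floored)
}

#' Normalised per-trial likelihood score
#'
#' Per-step average log-likelihood relative to a uniform random walk over the
#' available transitions: `(loglik - chance_loglik) / n_steps`. 0 means
#' random-walk-equivalent; positive means better than chance; `log(2)` means
#' twice the chance probability per step. Zero-step trials are undefined and
#' returned as `NA` with a message.
#'
#' @param trial_ll Data frame from [forced_walk_loglik()].
#' @return Numeric vector of normalised scores, one per trial.
#' @export
normalize_loglik <- function(trial_ll) {
  zero <- trial_ll$n_steps == 0L
  if (any(zero)) {
    message(sum(zero), " zero-step trial(s) excluded from normalised scores")
  }
  out <- ifelse(zero, NA_real_,
                (trial_ll$loglik - trial_ll$chance_loglik) / trial_ll$n_steps)
  out
}

# Fixed low-discrepancy optimizer starts over the bounds.
fit_starts <- function(kind, n_starts, alpha_bounds, gamma_bounds) {
  i <- seq_len(n_starts)
  a <- alpha_bounds[1L] + van_der_corput(i, 2) * diff(alpha_bounds)
  g <- gamma_bounds[1L] + van_der_corput(i, 3) * diff(gamma_bounds)
  if (kind == "MB") cbind(gamma = gamma_bounds[1L] + van_der_corput(i, 2) * diff(gamma_bounds))
  else cbind(alpha = a, gamma = g)
}

#' Maximum-likelihood parameter estimates for one agent kind
#'
#' Multi-start bounded minimisation of the negative forced-walk
#' log-likelihood with `stats::optim(method = "L-BFGS-B")`. MF and SR fit
#' `(alpha, gamma)`; MB fits `gamma` only (its model update has no learning
#' rate). Starts come from a fixed low-discrepancy grid over the bounds, so
#' the fit is deterministic; `seed` is recorded in the diagnostics.
#'
#' @param subject A `subject_data`.
#' @param schedule The `experiment_schedule`.
#' @param kind `"MF"`, `"MB"` or `"SR"`.
#' @param beta Softmax inverse temperature held fixed (default 1).
#' @param lambda Eligibility decay held fixed (default 0.5).
#' @param alpha_bounds,gamma_bounds Box constraints; gamma capped at 0.99 to
#'   keep values finite and the SR inversion well-conditioned.
#' @param n_starts Number of optimizer starts (default 5).
#' @param control Passed to `stats::optim`.
#' @param seed Recorded for provenance (the fit itself is deterministic).
#' @return Object of class `fit_result`: `kind`, `alpha` (`NA` for MB),
#'   `gamma`, `total_ll`, `trial_ll` (per-trial data frame), `unidentifiable`
#'   flag (every step had a single candidate), and `diagnostics` (start
#'   values, per-start convergence, seed).
#' @export
fit_parameters <- function(subject, schedule, kind = c("MF", "MB", "SR"),
                           beta = 1, lambda = 0.5,
                           alpha_bounds = c(0, 1), gamma_bounds = c(0, 0.99),
                           n_starts = 5L, control = list(maxit = 60L, factr = 1e10),
                           seed = 1L) {
  kind <- match.arg(kind)
  plan <- build_walk_plan(subject, schedule)
  ncands <- unlist(lapply(plan, function(cfg) {
    lapply(cfg$trials, function(tr) if (tr$n_steps > 0L) tr$ncand else integer(0))
  }), use.names = FALSE)
  unident <- length(ncands) == 0L || all(ncands <= 1L)

  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  make_params <- function(x) {
    # optim's finite-difference gradient can probe just outside the box
    if (kind == "MB") {
      agent_params(kind, alpha = 0,
                   gamma = clamp(x[1L], gamma_bounds[1L], gamma_bounds[2L]),
                   lambda = lambda, beta = beta)
    } else {
      agent_params(kind,
                   alpha = clamp(x[1L], alpha_bounds[1L], alpha_bounds[2L]),
                   gamma = clamp(x[2L], gamma_bounds[1L], gamma_bounds[2L]),
                   lambda = lambda, beta = beta)
    }
  }
  nll <- function(x) {
    tl <- walk_loglik(make_params(x), plan)
    -sum(tl$loglik)
  }
  starts <- fit_starts(kind, n_starts, alpha_bounds, gamma_bounds)
  lower <- if (kind == "MB") gamma_bounds[1L] else c(alpha_bounds[1L], gamma_bounds[1L])
  upper <- if (kind == "MB") gamma_bounds[2L] else c(alpha_bounds[2L], gamma_bounds[2L])
  runs <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                 lower = lower, upper = upper, control = control)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  params <- make_params(best$par)
  trial_ll <- walk_loglik(params, plan)
  structure(
    list(kind = kind,
         alpha = if (kind == "MB") NA_real_ else unname(best$par[1L]),
         gamma = unname(best$par[if (kind == "MB") 1L else 2L]),
         beta = beta, lambda = lambda,
         total_ll = sum(trial_ll$loglik),
         trial_ll = trial_ll,
         unidentifiable = unident,
         diagnostics = list(
           starts = starts,
           values = vapply(runs, `[[`, numeric(1), "value"),
           convergence = vapply(runs, `[[`, numeric(1), "convergence"),
           seed = seed)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> alpha=%s gamma=%.4f total_ll=%.2f (%d trials)%s\n",
              x$kind, if (is.na(x$alpha)) "-" else sprintf("%.4f", x$alpha),
              x$gamma, x$total_ll, nrow(x$trial_ll),
              if (x$unidentifiable) " [unidentifiable]" else ""))
  invisible(x)
}

#' Compare fitted models for one subject
#'
#' Computes pairwise log likelihood ratios `ln(LR) = total_ll(A) -
#' total_ll(B)`, per-trial best-model labels (argmax of per-trial
#' log-likelihood; exact ties labelled `"tie"`), and per-model proportions of
#' best trials (ties excluded, with a message when any occur).
#'
#' @param fits Named list of `fit_result`s for the same subject and trials
#'   (names are the kinds).
#' @return List with `table` (kind, alpha, gamma, total_ll, n_best_trials,
#'   prop_best), `lnLR` (matrix), `per_trial` (config, trial, best label) and
#'   `n_ties`.
#' @export
compare_models <- function(fits) {
  kinds <- vapply(fits, `[[`, character(1), "kind")
  names(fits) <- kinds
  nt <- vapply(fits, function(f) nrow(f$trial_ll), integer(1))
  if (length(unique(nt)) != 1L) stop("fits cover mismatched trial sets")
  ll_mat <- vapply(fits, function(f) f$trial_ll$loglik, numeric(nt[1L]))
  best <- apply(ll_mat, 1L, function(r) {
    top <- which(r >= max(r) - 1e-9)
    if (length(top) > 1L) "tie" else kinds[top]
  })
  n_ties <- sum(best == "tie")
  if (n_ties > 0L) message(n_ties, " tied trial(s) excluded from proportions")
  denom <- sum(best != "tie")
  totals <- vapply(fits, `[[`, numeric(1), "total_ll")
  lnLR <- outer(totals, totals, `-`)
  dimnames(lnLR) <- list(kinds, kinds)
  tab <- data.frame(
    kind = kinds,
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    gamma = vapply(fits, `[[`, numeric(1), "gamma"),
    total_ll = totals,
    n_best_trials = vapply(kinds, function(k) sum(best == k), integer(1)),
    prop_best = vapply(kinds, function(k) {
      if (denom == 0L) NA_real_ else sum(best == k) / denom
    }, numeric(1)),
    row.names = NULL
  )
  per_trial <- data.frame(config = fits[[1L]]$trial_ll$config,
                          trial = fits[[1L]]$trial_ll$trial, best = best)
  list(table = tab, lnLR = lnLR, per_trial = per_trial, n_ties = n_ties)
}

#' Write a model-comparison table for several subjects to CSV
#'
#' One row per subject x model: `subject, model, alpha, gamma, total_ll,
#' n_best_trials, prop_best`.
#'
#' @param comparisons Named list (by subject id) of [compare_models()] results.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_comparison <- function(comparisons, path) {
  rows <- lapply(names(comparisons), function(sid) {
    tab <- comparisons[[sid]]$table
    names(tab)[names(tab) == "kind"] <- "model"
    cbind(subject = sid, tab)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
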