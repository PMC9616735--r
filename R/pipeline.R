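# Run configuration and the end-to-end fit -> simulate -> metrics pipeline.

#' Pipeline run configuration
#'
#' Bundles every knob of the analysis with defaults equal to the task
#' protocol: 10 x 10 grid, 25 configurations x 10 trials, a 45-transition step
#' cap (45 s at one module per second), epsilon decaying 0.1 -> 0.01 across
#' the trials of a configuration, lambda = 0.5, beta = 1, 100 simulation
#' replicates per configuration.
#'
#' @param schedule_path Path to a `schedule.txt` index (see
#'   [read_schedule()]), or `NULL` when `schedule` is given directly.
#' @param trajectories_path Path to the subject trajectory CSV, or `NULL`
#'   when `subjects` is given directly.
#' @param out_dir Output directory.
#' @param schedule,subjects Optional in-memory inputs overriding the paths.
#' @param kinds Agent kinds to fit and simulate.
#' @param n_replicates Simulation replicates per configuration.
#' @param step_cap Maximum transitions per trial.
#' @param eps_start,eps_end Epsilon-decay endpoints.
#' @param lambda,beta Fixed trace-decay and softmax temperature.
#' @param n_starts Optimizer starts per fit.
#' @param seed Master seed fanned out to all stochastic stages via
#'   [child_seed()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(schedule_path = NULL, trajectories_path = NULL,
                       out_dir = "mazerl-out", schedule = NULL,
                       subjects = NULL, kinds = c("MF", "MB", "SR"),
                       n_replicates = 100L, step_cap = 45L, eps_start = 0.1,
                       eps_end = 0.01, lambda = 0.5, beta = 1, n_starts = 5L,
                       seed = 1L) {
  structure(list(schedule_path = schedule_path,
                 trajectories_path = trajectories_path, out_dir = out_dir,
                 schedule = schedule, subjects = subjects, kinds = kinds,
                 n_replicates = as.integer(n_replicates),
                 step_cap = as.integer(step_cap), eps_start = eps_start,
                 eps_end = eps_end, lambda = lambda, beta = beta,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline: fit, simulate, metrics
#'
#' For every subject and agent kind: fits maximum-likelihood parameters to
#' the subject's forced trajectories, simulates replicate agents trained on
#' the subject's history with those parameters, and computes per-configuration
#' comparison metrics (goal rates, occupancy correlation, Mahalanobis
#' dissimilarity of diffusivity features, minimum path-distance similarity).
#' Writes `fits.csv`, `comparison.csv`, `metrics.csv`, simulated trajectories
#' (`sim_<kind>.csv`) and a `manifest.json` echoing the configuration and
#' derived seeds. Input validation failures abort before any computation.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  schedule <- config$schedule
  if (is.null(schedule)) {
    if (is.null(config$schedule_path) || !file.exists(config$schedule_path)) {
      stop("schedule file not found: ", config$schedule_path)
    }
    schedule <- read_schedule(config$schedule_path)
  }
  subjects <- config$subjects
  if (is.null(subjects)) {
    if (is.null(config$trajectories_path) || !file.exists(config$trajectories_path)) {
      stop("trajectory file not found: ", config$trajectories_path)
    }
    subjects <- read_trajectories(config$trajectories_path, schedule = schedule)
  }
  if (inherits(subjects, "subject_data")) subjects <- list(subjects)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  fit_rows <- list()
  comparisons <- list()
  metric_rows <- list()
  all_sims <- list()
  for (sub in subjects) {
    sid <- sub$subject_id
    fits <- lapply(config$kinds, function(kind) {
      fit_parameters(sub, schedule, kind, beta = config$beta,
                     lambda = config$lambda, n_starts = config$n_starts,
                     seed = child_seed(config$seed, sid, kind, "fit"))
    })
    names(fits) <- config$kinds
    comparisons[[as.character(sid)]] <- compare_models(fits)
    for (f in fits) {
      fit_rows[[length(fit_rows) + 1L]] <-
        data.frame(subject = sid, model = f$kind, alpha = f$alpha,
                   gamma = f$gamma, total_ll = f$total_ll)
    }
    run <- run_experiment(sub, fits, schedule, kinds = config$kinds,
                          n_replicates = config$n_replicates,
                          step_cap = config$step_cap,
                          eps_start = config$eps_start,
                          eps_end = config$eps_end, seed = config$seed)
    all_sims[[as.character(sid)]] <- run
    nc <- schedule$configs[[1L]]$nc
    n_states <- length(schedule$configs[[1L]]$present)
    for (kind in config$kinds) {
      for (k in seq_along(schedule$configs)) {
        maze <- schedule$configs[[k]]
        reps <- run$sims[[kind]][[k]]
        sub_trials <- sub$trials[[k]]
        sub_rate <- goal_rate(sub_trials)
        agent_rate <- mean(vapply(reps, goal_rate, numeric(1)))
        occ <- tryCatch(
          occupancy_correlation(occupancy_map(sub_trials, n_states),
                                occupancy_map(unlist(reps, recursive = FALSE),
                                              n_states)),
          error = function(e) NA_real_)
        feats_sub <- config_diffusivity(sub_trials, nc)
        cluster <- t(vapply(reps, config_diffusivity, numeric(3), nc = nc))
        maha <- tryCatch(mahalanobis_dissimilarity(feats_sub, cluster),
                         error = function(e) NA_real_)
        mpd <- mean(vapply(seq_along(sub_trials), function(t) {
          as.numeric(min_path_distance_similarity(
            sub_trials[[t]], lapply(reps, `[[`, t), maze))
        }, numeric(1)))
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          subject = sid, kind = kind, config = k,
          subject_goal_rate = sub_rate, agent_goal_rate = agent_rate,
          occupancy_correlation = occ, mahalanobis = maha,
          min_path_distance = mpd)
      }
    }
  }

  utils::write.csv(do.call(rbind, fit_rows), file.path(config$out_dir, "fits.csv"),
                   row.names = FALSE, quote = FALSE)
  write_comparison(comparisons, file.path(config$out_dir, "comparison.csv"))
  utils::write.csv(do.call(rbind, metric_rows),
                   file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  for (kind in config$kinds) {
    sim_subjects <- lapply(names(all_sims), function(sid) {
      run <- all_sims[[sid]]
      trials <- lapply(seq_along(run$sims[[kind]]), function(k) {
        # replicate-major flattening: one pseudo-trial row set per replicate
        unlist(lapply(seq_along(run$sims[[kind]][[k]]), function(r) {
          run$sims[[kind]][[k]][[r]]
        }), recursive = FALSE)
      })
      subject_data(paste0(sid, "-", kind), species = "agent", trials = trials)
    })
    write_trajectories(sim_subjects, file.path(config$out_dir,
                                               paste0("sim_", kind, ".csv")),
                       nc = schedule$configs[[1L]]$nc)
  }
  manifest <- list(
    package = "mazerl",
    version = as.character(utils::packageVersion("mazerl")),
    seed = config$seed,
    kinds = config$kinds,
    n_replicates = config$n_replicates,
    step_cap = config$step_cap,
    eps = c(config$eps_start, config$eps_end),
    lambda = config$lambda, beta = config$beta,
    n_configs = length(schedule$configs),
    n_trials = n_trials(schedule),
    subjects = vapply(subjects, `[[`, character(1), "subject_id"),
    outputs = c("fits.csv", "comparison.csv", "metrics.csv",
                paste0("sim_", config$kinds, ".csv")),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
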