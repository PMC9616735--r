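# Experiment schedules, trajectories, subjects, and their plain-text formats.

#' Build an experiment schedule
#'
#' An ordered list of maze configurations, each with an ordered list of trial
#' start states. Iteration order is configuration-major, trial-minor. The goal
#' must be identical across configurations (the task keeps one hidden goal
#' fixed relative to the distal cue).
#'
#' @param configs List of `maze_config` objects.
#' @param starts List parallel to `configs`; each element either an integer
#'   vector of start states or a 2-column matrix of 0-based `(row, col)`
#'   coordinates, one row per trial.
#' @return An object of class `experiment_schedule` with fields `configs`,
#'   `starts` (integer state vectors) and `trials_per_config`.
#' @export
make_schedule <- function(configs, starts) {
  if (length(configs) != length(starts)) {
    stop("`configs` and `starts` must have the same length")
  }
  if (!length(configs)) stop("schedule must contain at least one configuration")
  goals <- vapply(configs, `[[`, integer(1), "goal")
  if (length(unique(goals)) != 1L) {
    stop("all configurations in a schedule must share the same goal location")
  }
  starts <- lapply(seq_along(starts), function(k) {
    s <- starts[[k]]
    m <- configs[[k]]
    if (is.matrix(s)) s <- rc_state(s[, 1L], s[, 2L], m$nc)
    s <- as.integer(s)
    if (!length(s)) stop("configuration ", k, " has no start states")
    bad <- !m$present[s]
    if (any(bad)) {
      stop("configuration ", k, ": start state(s) ",
           paste(s[bad], collapse = ", "), " placed on removed module(s)")
    }
    if (any(s == m$goal)) {
      stop("configuration ", k, ": a start state coincides with the goal")
    }
    s
  })
  structure(
    list(configs = configs, starts = starts,
         trials_per_config = lengths(starts)),
    class = "experiment_schedule"
  )
}

#' Total number of trials in a schedule
#'
#' @param schedule An `experiment_schedule`.
#' @return Integer trial count (sum over configurations).
#' @export
n_trials <- function(schedule) {
  sum(schedule$trials_per_config)
}

#' @export
print.experiment_schedule <- function(x, ...) {
  cat(sprintf("<experiment_schedule> %d configurations, %d trials total\n",
              length(x$configs), n_trials(x)))
  invisible(x)
}

#' Write / read a schedule directory
#'
#' `write_schedule` saves each configuration as a maze file
#' (`config_01.maze`, ...) plus a `schedule.txt` index whose non-comment lines
#' are `<maze file> r,c r,c ...` (whitespace separated, 0-based coordinates,
#' `#` comments). `read_schedule` parses such an index, resolving maze paths
#' relative to the index file.
#'
#' @param schedule An `experiment_schedule`.
#' @param dir Directory to write into (created if needed).
#' @return `write_schedule` returns the index path invisibly; `read_schedule`
#'   returns an `experiment_schedule`.
#' @export
write_schedule <- function(schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# schedule: <maze file> r,c r,c ...  (0-based row,col per trial)")
  for (k in seq_along(schedule$configs)) {
    fn <- sprintf("config_%02d.maze", k)
    save_maze(schedule$configs[[k]], file.path(dir, fn))
    rc <- state_rc(schedule$starts[[k]], schedule$configs[[k]]$nc)
    lines <- c(lines, paste(fn, paste(rc[, "row"], rc[, "col"], sep = ",",
                                      collapse = " ")))
  }
  idx <- file.path(dir, "schedule.txt")
  writeLines(lines, idx)
  invisible(idx)
}

#' @rdname write_schedule
#' @param path Path to a `schedule.txt` index file.
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  base <- dirname(path)
  configs <- list()
  starts <- list()
  for (ln in lines) {
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    maze <- read_maze(file.path(base, toks[1L]))
    rc <- do.call(rbind, lapply(toks[-1L], function(t) {
      as.integer(strsplit(t, ",", fixed = TRUE)[[1L]])
    }))
    configs[[length(configs) + 1L]] <- maze
    starts[[length(starts) + 1L]] <- rc
  }
  make_schedule(configs, starts)
}

#' Construct a trajectory
#'
#' An ordered sequence of module entries for one trial. Consecutive states
#' must be orthogonally adjacent and present when `validate = TRUE`.
#'
#' @param states Integer vector of states (module entries), length >= 1.
#' @param maze The `maze_config` the trial ran on (used for validation and the
#'   `goal_reached` flag); may be `NULL`.
#' @param subject_id,config_index,trial_index Identifiers (1-based indices).
#' @param validate Check adjacency/presence against `maze`.
#' @return Object of class `trajectory` with fields `states`, `subject_id`,
#'   `config_index`, `trial_index`, `goal_reached`.
#' @export
trajectory <- function(states, maze = NULL, subject_id = NA_character_,
                       config_index = NA_integer_, trial_index = NA_integer_,
                       validate = TRUE) {
  states <- as.integer(states)
  if (!length(states)) stop("a trajectory must contain at least one state")
  goal_reached <- NA
  if (!is.null(maze)) {
    if (validate) validate_trajectory(states, maze)
    goal_reached <- states[length(states)] == maze$goal
  }
  structure(
    list(states = states, subject_id = subject_id,
         config_index = as.integer(config_index),
         trial_index = as.integer(trial_index),
         goal_reached = goal_reached),
    class = "trajectory"
  )
}

#' Validate a state sequence against a maze
#'
#' Checks that every state is present and that consecutive states are
#' orthogonally adjacent; optionally checks the step cap.
#'
#' @param states Integer state sequence.
#' @param maze A `maze_config`.
#' @param step_cap Optional maximum number of transitions.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_trajectory <- function(states, maze, step_cap = NULL) {
  if (any(states < 1L | states > length(maze$present))) {
    stop("trajectory contains states outside the grid")
  }
  if (any(!maze$present[states])) {
    stop("trajectory visits removed module(s): ",
         paste(states[!maze$present[states]], collapse = ", "))
  }
  if (length(states) > 1L) {
    from <- states[-length(states)]
    to <- states[-1L]
    ok <- maze$nbr[cbind(action_between(from, to, maze$nc), from)] == to
    if (any(!ok | is.na(ok))) stop("trajectory contains a non-adjacent step")
  }
  if (!is.null(step_cap) && length(states) - 1L > step_cap) {
    stop("trajectory exceeds the step cap of ", step_cap)
  }
  invisible(TRUE)
}

#' Bundle a subject's trajectories over a full schedule
#'
#' @param subject_id Identifier.
#' @param species Label (e.g. "rat", "human", "synthetic").
#' @param trials Nested list: `trials[[config]][[trial]]` is a `trajectory`;
#'   must match the schedule's trial counts when `schedule` is supplied.
#' @param schedule Optional `experiment_schedule` for validation.
#' @return Object of class `subject_data`.
#' @export
subject_data <- function(subject_id, species = "unknown", trials = list(),
                         schedule = NULL) {
  if (!is.null(schedule)) {
    if (length(trials) != length(schedule$configs)) {
      stop("subject has ", length(trials), " configurations, schedule has ",
           length(schedule$configs))
    }
    for (k in seq_along(trials)) {
      if (length(trials[[k]]) != schedule$trials_per_config[k]) {
        stop("configuration ", k, ": expected ",
             schedule$trials_per_config[k], " trials, got ", length(trials[[k]]))
      }
      for (t in seq_along(trials[[k]])) {
        tr <- trials[[k]][[t]]
        validate_trajectory(tr$states, schedule$configs[[k]])
        if (tr$states[1L] != schedule$starts[[k]][t]) {
          stop("configuration ", k, " trial ", t,
               ": trajectory does not begin at the scheduled start")
        }
      }
    }
  }
  structure(list(subject_id = subject_id, species = species, trials = trials),
            class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("<subject_data '%s' (%s)> %d configurations, %d trials\n",
              x$subject_id, x$species, length(x$trials),
              sum(lengths(x$trials))))
  invisible(x)
}

#' Convert subjects to / from the tidy trajectory table
#'
#' The on-disk format is a CSV with header
#' `subject_id, config_index, trial_index, step_index, row, col`; all indices
#' are 0-based integers.
#'
#' @param subjects A `subject_data` or list of them.
#' @return `trajectories_to_df` returns a data.frame in the format above
#'   (with 0-based indices); `trajectories_from_df` the inverse.
#' @export
trajectories_to_df <- function(subjects) {
  if (inherits(subjects, "subject_data")) subjects <- list(subjects)
  out <- lapply(subjects, function(sub) {
    rows <- lapply(seq_along(sub$trials), function(k) {
      lapply(seq_along(sub$trials[[k]]), function(t) {
        st <- sub$trials[[k]][[t]]$states
        data.frame(
          subject_id = sub$subject_id,
          config_index = k - 1L,
          trial_index = t - 1L,
          step_index = seq_along(st) - 1L,
          state = st
        )
      })
    })
    do.call(rbind, unlist(rows, recursive = FALSE))
  })
  do.call(rbind, out)
}

#' Write subject trajectories to the standard CSV
#'
#' @param subjects `subject_data` or list of them.
#' @param path Output CSV path.
#' @param nc Number of grid columns (to convert states to row/col).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(subjects, path, nc = 10L) {
  df <- trajectories_to_df(subjects)
  rc <- state_rc(df$state, nc)
  out <- data.frame(subject_id = df$subject_id, config_index = df$config_index,
                    trial_index = df$trial_index, step_index = df$step_index,
                    row = rc[, "row"], col = rc[, "col"])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject trajectories from the standard CSV
#'
#' @param path CSV path (header `subject_id, config_index, trial_index,
#'   step_index, row, col`, 0-based).
#' @param schedule Optional `experiment_schedule`; when given, trajectories are
#'   validated against it and `goal_reached` flags are filled in.
#' @param nc Grid columns (ignored when `schedule` is given).
#' @param species Species label to attach.
#' @return Named list of `subject_data`, one per subject, in file order.
#' @export
read_trajectories <- function(path, schedule = NULL, nc = 10L,
                              species = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "config_index", "trial_index", "step_index", "row", "col")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(schedule)) nc <- schedule$configs[[1L]]$nc
  df$state <- rc_state(df$row, df$col, nc)
  subjects <- list()
  for (sid in unique(df$subject_id)) {
    d <- df[df$subject_id == sid, ]
    trials <- list()
    for (k in sort(unique(d$config_index))) {
      dk <- d[d$config_index == k, ]
      trials_k <- list()
      for (t in sort(unique(dk$trial_index))) {
        dt <- dk[dk$trial_index == t, ]
        dt <- dt[order(dt$step_index), ]
        maze <- if (!is.null(schedule)) schedule$configs[[k + 1L]] else NULL
        trials_k[[t + 1L]] <- trajectory(dt$state, maze = maze,
                                         subject_id = sid,
                                         config_index = k + 1L,
                                         trial_index = t + 1L)
      }
      trials[[k + 1L]] <- trials_k
    }
    subjects[[as.character(sid)]] <-
      subject_data(sid, species = species, trials = trials, schedule = schedule)
  }
  subjects
}

#' Discretise a continuous trajectory onto the module grid
#'
#' Maps sampled `(x, y)` positions to the sequence of modules entered.
#' Consecutive duplicates are collapsed. Module changes between samples are
#' resolved by walking the straight segment between the samples and recording
#' every grid-line crossing in order; a diagonal (corner) crossing is split
#' into two orthogonal steps through whichever intermediate module the segment
#' touches first, with exact corner ties resolved row-first.
#'
#' `x` runs along columns and `y` along rows (row 0 at `y = 0`), so the module
#' at position `(x, y)` is `(row, col) = (floor(y/w), floor(x/w))`.
#'
#' @param xy Two-column numeric matrix of sampled positions.
#' @param maze A `maze_config` giving the grid geometry.
#' @param module_width Width `w` of one module in position units.
#' @param ... Passed to [trajectory()] (identifiers, `validate`).
#' @return A `trajectory`.
#' @export
discretize_trajectory <- function(xy, maze, module_width = 1, ...) {
  xy <- as.matrix(xy)
  w <- module_width
  if (any(xy[, 1L] < 0 | xy[, 1L] > maze$nc * w |
          xy[, 2L] < 0 | xy[, 2L] > maze$nr * w)) {
    stop("position outside maze bounds")
  }
  mod_of <- function(p) {
    c(row = min(floor(p[2L] / w), maze$nr - 1),
      col = min(floor(p[1L] / w), maze$nc - 1))
  }
  cur <- mod_of(xy[1L, ])
  states <- rc_state(cur["row"], cur["col"], maze$nc)
  if (nrow(xy) > 1L) {
    for (i in seq_len(nrow(xy) - 1L)) {
      p <- xy[i, ]
      q <- xy[i + 1L, ]
      tgt <- mod_of(q)
      if (all(tgt == cur)) next
      # grid-line crossing times along the segment p -> q
      ev_t <- numeric(0)
      ev_axis <- integer(0)   # 0 = row crossing, 1 = col crossing
      ev_dir <- integer(0)
      dy <- q[2L] - p[2L]
      if (dy != 0 && tgt[["row"]] != cur[["row"]]) {
        ks <- if (dy > 0) seq(cur[["row"]] + 1L, tgt[["row"]]) else
                          seq(cur[["row"]], tgt[["row"]] + 1L)
        tt <- (ks * w - p[2L]) / dy
        ev_t <- c(ev_t, tt)
        ev_axis <- c(ev_axis, rep(0L, length(tt)))
        ev_dir <- c(ev_dir, rep(if (dy > 0) 1L else -1L, length(tt)))
      }
      dx <- q[1L] - p[1L]
      if (dx != 0 && tgt[["col"]] != cur[["col"]]) {
        ks <- if (dx > 0) seq(cur[["col"]] + 1L, tgt[["col"]]) else
                          seq(cur[["col"]], tgt[["col"]] + 1L)
        tt <- (ks * w - p[1L]) / dx
        ev_t <- c(ev_t, tt)
        ev_axis <- c(ev_axis, rep(1L, length(tt)))
        ev_dir <- c(ev_dir, rep(if (dx > 0) 1L else -1L, length(tt)))
      }
      ord <- order(ev_t, ev_axis)  # corner tie: row crossing first
      for (j in ord) {
        if (ev_axis[j] == 0L) cur[["row"]] <- cur[["row"]] + ev_dir[j]
        else cur[["col"]] <- cur[["col"]] + ev_dir[j]
        states <- c(states, rc_state(cur[["row"]], cur[["col"]], maze$nc))
      }
    }
  }
  states <- states[c(TRUE, diff(states) != 0L)]
  trajectory(states, maze = maze, ...)
}
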