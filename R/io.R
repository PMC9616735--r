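# Serialization of agent state, fit results, and occupancy maps to
# plain-text formats.

#' Checkpoint an agent to / from a JSON file
#'
#' The file holds the agent's kind, parameters, grid geometry, and learned
#' structures as flat arrays (`Q` and `M` in row-major order, `chi` as 0/1),
#' so simulations can checkpoint between configurations and resume
#' elsewhere. Eligibility traces are part of the checkpoint so a mid-trial
#' state round-trips exactly.
#'
#' @param agent An `rl_agent`.
#' @param path Output path.
#' @return `save_agent` returns `path` invisibly; `read_agent` an `rl_agent`.
#' @export
save_agent <- function(agent, path) {
  obj <- list(
    kind = agent$kind,
    params = unclass(agent$params),
    nr = agent$nr, nc = agent$nc,
    Q = if (!is.null(agent$Q)) as.vector(t(agent$Q)),
    e_sa = if (!is.null(agent$e_sa)) as.vector(t(agent$e_sa)),
    M = if (!is.null(agent$M)) as.vector(t(agent$M)),
    e_s = agent$e_s,
    chi = if (!is.null(agent$chi)) as.integer(agent$chi)
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_agent
#' @export
read_agent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(agent_params, as.list(obj$params))
  n <- obj$nr * obj$nc
  agent <- structure(
    list(kind = obj$kind, params = params, nr = obj$nr, nc = obj$nc, n = n,
         Q = NULL, e_sa = NULL, M = NULL, e_s = NULL, chi = NULL,
         chi_version = 0L, cache = NULL),
    class = "rl_agent"
  )
  if (!is.null(obj$Q)) {
    agent$Q <- matrix(obj$Q, n, 4L, byrow = TRUE)
    agent$e_sa <- matrix(obj$e_sa, n, 4L, byrow = TRUE)
  }
  if (!is.null(obj$M)) {
    agent$M <- matrix(obj$M, n, n, byrow = TRUE)
    agent$e_s <- obj$e_s
  }
  if (!is.null(obj$chi)) {
    agent$chi <- as.logical(obj$chi)
    agent$cache <- new.env(parent = emptyenv())
  }
  agent
}

#' Serialize a fit result to / from a JSON file
#'
#' Stores the fitted parameters, total and per-trial log-likelihoods, and
#' optimizer diagnostics in a structured text file.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `save_fit_result` returns `path` invisibly; `read_fit_result` a
#'   `fit_result`.
#' @export
save_fit_result <- function(fit, path) {
  obj <- list(kind = fit$kind, alpha = fit$alpha, gamma = fit$gamma,
              beta = fit$beta, lambda = fit$lambda, total_ll = fit$total_ll,
              unidentifiable = fit$unidentifiable,
              trial_ll = as.data.frame(fit$trial_ll),
              diagnostics = list(
                starts = as.data.frame(fit$diagnostics$starts),
                values = fit$diagnostics$values,
                convergence = fit$diagnostics$convergence,
                seed = fit$diagnostics$seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_fit_result
#' @export
read_fit_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$alpha <- if (is.null(obj$alpha)) NA_real_ else obj$alpha
  structure(obj, class = "fit_result")
}

#' Write / read an occupancy map as a dense grid of proportions
#'
#' One text row per grid row, whitespace-separated proportions, `#` comment
#' lines allowed.
#'
#' @param map Occupancy vector (length `nr * nc`, state-indexed).
#' @param path File path.
#' @param nr,nc Grid dimensions.
#' @return `write_occupancy` returns `path` invisibly; `read_occupancy` the
#'   occupancy vector.
#' @export
write_occupancy <- function(map, path, nr = 10L, nc = 10L) {
  stopifnot(length(map) == nr * nc)
  m <- matrix(map, nr, nc, byrow = TRUE)
  lines <- c(sprintf("# occupancy %dx%d", nr, nc),
             apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vals <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  as.vector(t(do.call(rbind, vals)))
}
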