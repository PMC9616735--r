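# Shared helpers: state indexing, lattice geometry, seed derivation.

.mazerl_env <- new.env(parent = emptyenv())

#' Convert (row, col) coordinates to flat state indices
#'
#' States are integers `1..nr*nc` in row-major order; rows and columns are
#' 0-based, matching the on-disk formats, so `state = row * nc + col + 1`.
#' Row 0 is the side of the grid bearing the distal cue.
#'
#' @param row,col Integer vectors of 0-based coordinates.
#' @param nc Number of grid columns.
#' @return Integer vector of state indices.
#' @export
rc_state <- function(row, col, nc) {
  as.integer(row) * as.integer(nc) + as.integer(col) + 1L
}

#' Convert flat state indices to (row, col) coordinates
#'
#' @param state Integer vector of state indices (1-based).
#' @param nc Number of grid columns.
#' @return Integer matrix with columns `row` and `col` (0-based).
#' @export
state_rc <- function(state, nc) {
  s0 <- as.integer(state) - 1L
  cbind(row = s0 %/% as.integer(nc), col = s0 %% as.integer(nc))
}

# 4 x n matrix of lattice neighbours in fixed action order (up, down, left,
# right); NA where the move leaves the grid. Memoised per grid size.
lattice_neighbors <- function(nr, nc) {
  key <- paste0("lat", nr, "x", nc)
  hit <- .mazerl_env[[key]]
  if (!is.null(hit)) return(hit)
  n <- nr * nc
  s <- seq_len(n)
  rc <- state_rc(s, nc)
  nbr <- rbind(
    up    = ifelse(rc[, "row"] > 0L,      s - nc, NA_integer_),
    down  = ifelse(rc[, "row"] < nr - 1L, s + nc, NA_integer_),
    left  = ifelse(rc[, "col"] > 0L,      s - 1L, NA_integer_),
    right = ifelse(rc[, "col"] < nc - 1L, s + 1L, NA_integer_)
  )
  storage.mode(nbr) <- "integer"
  .mazerl_env[[key]] <- nbr
  nbr
}

# Action index (1 = up, 2 = down, 3 = left, 4 = right) for a single-step
# transition between orthogonally adjacent states.
action_between <- function(from, to, nc) {
  d <- as.integer(to) - as.integer(from)
  a <- integer(length(d))
  a[d == -nc] <- 1L
  a[d == nc] <- 2L
  a[d == -1L] <- 3L
  a[d == 1L] <- 4L
  if (any(a == 0L)) stop("states are not orthogonally adjacent")
  a
}

#' Derive a child RNG seed from a master seed and a path of identifiers
#'
#' Deterministic fan-out of one master seed to independent stages (subject,
#' agent kind, replicate, ...), so partial re-runs are stable. Accepts integers
#' and character labels; the result is always in `[1, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param ... Integers or strings identifying the stage.
#' @return A single integer seed.
#' @export
child_seed <- function(master, ...) {
  parts <- c(as.double(master %% 2147483647), unlist(lapply(list(...), function(x) {
    if (is.character(x)) {
      vapply(x, function(str) sum(utf8ToInt(str) * seq_len(nchar(str))) %% 2147483647,
             numeric(1))
    } else {
      as.double(x) %% 2147483647
    }
  }), use.names = FALSE))
  h <- 104729
  for (p in parts) h <- (h * 69069 + p + 1) %% 2147483647
  as.integer(h %% 2147483645) + 1L
}

# Breadth-first distances over an arbitrary presence vector on the lattice.
# `nbr` is a 4 x n lattice-neighbour matrix; absent modules are impassable.
bfs_distances <- function(present, nbr, src) {
  n <- length(present)
  dist <- rep(NA_integer_, n)
  if (src < 1L || src > n || !present[src]) return(dist)
  dist[src] <- 0L
  queue <- integer(n)
  queue[1L] <- src
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    s <- queue[head]
    head <- head + 1L
    ds <- dist[s] + 1L
    for (a in 1:4) {
      t <- nbr[a, s]
      if (!is.na(t) && present[t] && is.na(dist[t])) {
        dist[t] <- ds
        tail <- tail + 1L
        queue[tail] <- t
      }
    }
  }
  dist
}

# van der Corput low-discrepancy sequence, used for fixed optimiser starts.
van_der_corput <- function(i, base) {
  vapply(i, function(k) {
    v <- 0
    f <- 1 / base
    while (k > 0) {
      v <- v + f * (k %% base)
      k <- k %/% base
      f <- f / base
    }
    v
  }, numeric(1))
}
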