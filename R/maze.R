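# Maze representation, file format, adjacency and optimal paths.

#' Construct a maze configuration
#'
#' A maze is a rectangular grid of modules, each present (traversable) or
#' removed (an impassable gap), with a single goal module that is always
#' present. Movement is 4-connected: up, down, left, right.
#'
#' @param present Logical (or 0/1) matrix, `nr x nc`; `TRUE` = module present.
#'   Matrix row `i` is grid row `i - 1` (0-based), so `present[1, 1]` is the
#'   module at (row 0, col 0).
#' @param goal Either a length-2 vector of 0-based `(row, col)` coordinates or
#'   a single flat state index.
#' @param id Character label for the configuration.
#' @return An object of class `maze_config` with fields `present` (logical
#'   vector indexed by state), `nr`, `nc`, `goal` (state index), `id`, and
#'   `nbr` (4 x n matrix of present orthogonal neighbours in up/down/left/right
#'   order, `NA` where blocked or off-grid).
#' @export
maze_config <- function(present, goal, id = "maze") {
  if (!is.matrix(present)) stop("`present` must be a matrix")
  nr <- nrow(present)
  nc <- ncol(present)
  pres <- as.vector(t(present)) != 0
  if (!any(pres)) stop("maze must contain at least one present module")
  if (length(goal) == 2L) goal <- rc_state(goal[1L], goal[2L], nc)
  goal <- as.integer(goal)
  if (goal < 1L || goal > nr * nc) stop("goal lies outside the grid")
  if (!pres[goal]) stop("goal module must be present")
  nbr <- lattice_neighbors(nr, nc)
  idx <- which(!is.na(nbr))
  blocked <- idx[!pres[nbr[idx]]]
  if (length(blocked)) nbr[blocked] <- NA_integer_
  structure(
    list(present = pres, nr = nr, nc = nc, goal = goal, id = id, nbr = nbr),
    class = "maze_config"
  )
}

#' Fully open maze
#'
#' The training-phase layout: every module present.
#'
#' @param nr,nc Grid dimensions (default 10 x 10).
#' @param goal Goal as 0-based `(row, col)` or a state index.
#' @param id Label.
#' @return A `maze_config`.
#' @export
open_maze <- function(nr = 10L, nc = 10L, goal = c(2L, 7L), id = "open") {
  maze_config(matrix(TRUE, nr, nc), goal, id = id)
}

#' @export
print.maze_config <- function(x, ...) {
  cat(sprintf("<maze_config '%s'> %dx%d, %d present, goal at (%d,%d)\n",
              x$id, x$nr, x$nc, sum(x$present),
              state_rc(x$goal, x$nc)[1L], state_rc(x$goal, x$nc)[2L]))
  cat(write_maze(x))
  invisible(x)
}

#' Presence matrix of a maze
#'
#' @param maze A `maze_config`.
#' @return Logical `nr x nc` matrix (matrix row 1 = grid row 0).
#' @export
maze_matrix <- function(maze) {
  matrix(maze$present, maze$nr, maze$nc, byrow = TRUE)
}

#' Parse a maze from its text representation
#'
#' One character per module per line: `X` = present, `.` = removed, `G` = the
#' goal (present). Exactly one `G` and equal-length rows are required. The
#' representation round-trips through [write_maze()].
#'
#' @param text A single string (rows separated by newlines) or a character
#'   vector of rows.
#' @param id Label for the configuration.
#' @return A `maze_config`.
#' @export
parse_maze <- function(text, id = "maze") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text <- text[!(seq_along(text) == length(text) & text == "")]  # trailing blank
  if (!length(text)) stop("empty maze text")
  widths <- nchar(text)
  if (length(unique(widths)) != 1L) {
    stop("ragged rows: all rows must have the same length")
  }
  chars <- do.call(rbind, strsplit(text, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(chars)), c("X", ".", "G"))
  if (length(bad)) stop("unknown maze character(s): ", paste(bad, collapse = " "))
  ngoal <- sum(chars == "G")
  if (ngoal != 1L) stop("maze must contain exactly one goal 'G', found ", ngoal)
  goal_idx <- which(chars == "G", arr.ind = TRUE)
  maze_config(chars != ".", c(goal_idx[1L, 1L] - 1L, goal_idx[1L, 2L] - 1L), id = id)
}

#' Write a maze to its text representation
#'
#' @param maze A `maze_config`.
#' @return A single string, rows separated by `\n`, with a trailing newline.
#' @export
write_maze <- function(maze) {
  ch <- ifelse(maze$present, "X", ".")
  ch[maze$goal] <- "G"
  rows <- apply(matrix(ch, maze$nr, maze$nc, byrow = TRUE), 1L, paste, collapse = "")
  paste0(paste(rows, collapse = "\n"), "\n")
}

#' Read / save a maze file
#'
#' @param path File path.
#' @param id Label (defaults to the file name).
#' @return `read_maze` returns a `maze_config`; `save_maze` returns `path`
#'   invisibly.
#' @export
read_maze <- function(path, id = basename(path)) {
  parse_maze(readLines(path), id = id)
}

#' @rdname read_maze
#' @param maze A `maze_config`.
#' @export
save_maze <- function(maze, path) {
  cat(write_maze(maze), file = path)
  invisible(path)
}

#' Present orthogonal neighbours of a state
#'
#' The locally available transitions: the up/down/left/right neighbours that
#' are inside the grid and present. No diagonals.
#'
#' @param maze A `maze_config`.
#' @param state State index; must be a present module.
#' @return Sorted integer vector of neighbouring states (possibly empty).
#' @export
adjacent_states <- function(maze, state) {
  if (state < 1L || state > length(maze$present) || !maze$present[state]) {
    stop("state ", state, " is not present in the maze")
  }
  ns <- maze$nbr[, state]
  sort(ns[!is.na(ns)])
}

#' Breadth-first distances from a state
#'
#' @param maze A `maze_config`.
#' @param from Source state (present).
#' @return Integer vector of shortest-path lengths (in state transitions) from
#'   `from` to every state; `NA` where unreachable.
#' @export
distance_map <- function(maze, from) {
  if (!maze$present[from]) stop("source state is not present in the maze")
  bfs_distances(maze$present, lattice_neighbors(maze$nr, maze$nc), from)
}

#' Shortest path between two states (A* search)
#'
#' A* on the 4-connected lattice with the Manhattan-distance heuristic, which
#' is admissible here, so returned lengths are exactly optimal. Among equally
#' short paths ties are broken by the fixed action order up, down, left,
#' right; only the length is contract-bearing. Unreachability is signalled by
#' `length = NA`, not an error, so metrics can aggregate failed layouts.
#'
#' @param maze A `maze_config`.
#' @param src,dst Present states.
#' @return List with `length` (integer, in state transitions; `NA` if
#'   unreachable) and `path` (integer state sequence from `src` to `dst`, or
#'   `NULL` if unreachable).
#' @export
shortest_path <- function(maze, src, dst) {
  if (!maze$present[src]) stop("src is not present in the maze")
  if (!maze$present[dst]) stop("dst is not present in the maze")
  if (src == dst) return(list(length = 0L, path = src))
  n <- length(maze$present)
  rc <- state_rc(seq_len(n), maze$nc)
  h <- abs(rc[, "row"] - rc[dst, "row"]) + abs(rc[, "col"] - rc[dst, "col"])
  g <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  open <- logical(n)
  closed <- logical(n)
  g[src] <- 0
  open[src] <- TRUE
  while (any(open)) {
    cand <- which(open)
    f <- g[cand] + h[cand]
    # deterministic selection: min f, then min h, then lowest state index
    best <- cand[order(f, h[cand], cand)[1L]]
    if (best == dst) {
      path <- dst
      s <- dst
      while (!is.na(parent[s])) {
        s <- parent[s]
        path <- c(s, path)
      }
      return(list(length = as.integer(g[dst]), path = as.integer(path)))
    }
    open[best] <- FALSE
    closed[best] <- TRUE
    for (a in 1:4) {
      t <- maze$nbr[a, best]
      if (is.na(t) || closed[t]) next
      gt <- g[best] + 1
      if (gt < g[t]) {
        g[t] <- gt
        parent[t] <- best
        open[t] <- TRUE
      }
    }
  }
  list(length = NA_integer_, path = NULL)
}

#' Tortuosity of the optimal route between two states
#'
#' Shortest-path length in module steps divided by the Euclidean distance
#' between the module centres in module widths. 1 means the optimal route is
#' as direct as geometry allows; larger values indicate forced detours.
#'
#' @param maze A `maze_config`.
#' @param start Start state (present, not the goal).
#' @param goal Target state; defaults to the maze goal.
#' @return Numeric ratio `>= 1` up to lattice quantisation.
#' @export
tortuosity <- function(maze, start, goal = maze$goal) {
  if (start == goal) stop("tortuosity is undefined for start = goal")
  len <- shortest_path(maze, start, goal)$length
  if (is.na(len)) stop("goal is unreachable from start")
  rc <- state_rc(c(start, goal), maze$nc)
  eucl <- sqrt(sum((rc[1L, ] - rc[2L, ])^2))
  len / eucl
}

#' Diameter of a maze
#'
#' The largest finite shortest-path length between any two present modules.
#' Used to cap unreachable distances in trajectory-similarity metrics.
#'
#' @param maze A `maze_config`.
#' @return Integer diameter.
#' @export
maze_diameter <- function(maze) {
  lat <- lattice_neighbors(maze$nr, maze$nc)
  dmax <- 0L
  for (s in which(maze$present)) {
    d <- bfs_distances(maze$present, lat, s)
    m <- suppressWarnings(max(d, na.rm = TRUE))
    if (m > dmax) dmax <- m
  }
  as.integer(dmax)
}
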