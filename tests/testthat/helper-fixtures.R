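# Shared fixtures and independent oracles used across the suite.

# Independent breadth-first-search oracle for shortest-path lengths.
# Deliberately written against the raw presence matrix, not the package's
# neighbour tables.
bfs_oracle <- function(present_mat, src_rc, dst_rc) {
  nr <- nrow(present_mat)
  nc <- ncol(present_mat)
  dist <- matrix(NA_integer_, nr, nc)
  if (!present_mat[src_rc[1] + 1, src_rc[2] + 1]) return(NA_integer_)
  dist[src_rc[1] + 1, src_rc[2] + 1] <- 0L
  queue <- list(src_rc)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    d <- dist[cur[1] + 1, cur[2] + 1]
    for (mv in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nr_ <- cur[1] + mv[1]
      nc_ <- cur[2] + mv[2]
      if (nr_ < 0 || nr_ >= nr || nc_ < 0 || nc_ >= nc) next
      if (!present_mat[nr_ + 1, nc_ + 1]) next
      if (!is.na(dist[nr_ + 1, nc_ + 1])) next
      dist[nr_ + 1, nc_ + 1] <- d + 1L
      queue[[length(queue) + 1]] <- c(nr_, nc_)
    }
  }
  dist[dst_rc[1] + 1, dst_rc[2] + 1]
}

# 4x4 maze whose (0,0) -> goal route needs a 5-step detour for a Euclidean
# distance of 3 (goal at (0,3), module (0,1) removed).
detour_maze <- function() {
  parse_maze(c("X.XG",
               "XXXX",
               "XXXX",
               "XXXX"), id = "detour-4x4")
}

# Small open 4x4 maze with the goal in a corner.
open4 <- function() open_maze(4, 4, goal = c(3, 3), id = "open-4x4")

# A random valid 10x10 configuration with a reachable goal (fast rejection).
random_maze <- function(p_remove = 0.25, goal = c(2, 7)) {
  repeat {
    pres <- matrix(stats::runif(100) > p_remove, 10, 10)
    pres[goal[1] + 1, goal[2] + 1] <- TRUE
    m <- maze_config(pres, goal)
    d <- distance_map(m, m$goal)
    if (sum(!is.na(d)) > 30) return(m)
  }
}

# Tiny two-config schedule on a 6x6 grid for fast end-to-end runs.
mini_schedule <- function(seed = 101, n_configs = 2) {
  generate_maze_sequence(n_configs = n_configs, nr = 6, nc = 6, goal = c(1, 4),
                         density_range = c(0.15, 0.25), n_starts = 5,
                         min_tortuosity = 1.05, min_max_tortuosity = 1.2,
                         seed = seed)
}
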