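# Maze representation, file format, adjacency, optimal paths, schedules,
# and trajectory discretisation.

test_that("maze text format parses and round-trips", {
  txt <- paste0(paste(c("XXXXXXXXXX", rep("XXXXXXXXXX", 8),
                        "XXXXXXXGXX")[c(1:9, 10)], collapse = "\n"), "\n")
  m <- parse_maze(txt)
  expect_equal(sum(m$present), 100L)
  expect_equal(dim(maze_matrix(m)), c(10L, 10L))
  expect_identical(write_maze(m), txt)

  # parse(write(m)) = m for random mazes
  set.seed(7)
  for (i in 1:10) {
    m <- random_maze()
    m2 <- parse_maze(write_maze(m), id = m$id)
    expect_identical(m2$present, m$present)
    expect_identical(m2$goal, m$goal)
  }
})

test_that("malformed maze text is rejected", {
  expect_error(parse_maze(c("XXX", "XXGX")), "ragged")
  expect_error(parse_maze(c("XXX", "XXX")), "exactly one goal")
  expect_error(parse_maze(c("XGX", "XGX")), "exactly one goal")
  expect_error(parse_maze(c("XAX", "XGX")), "unknown")
  expect_error(maze_config(matrix(FALSE, 2, 2), c(0, 0)), "present")
})

test_that("adjacent_states returns present orthogonal neighbours only", {
  m <- open_maze()
  expect_setequal(adjacent_states(m, rc_state(0, 0, 10)),
                  c(rc_state(0, 1, 10), rc_state(1, 0, 10)))
  expect_length(adjacent_states(m, rc_state(5, 5, 10)), 4L)

  # module with all four neighbours removed
  pres <- matrix(TRUE, 5, 5)
  for (rc in list(c(1, 2), c(3, 2), c(2, 1), c(2, 3))) pres[rc[1] + 1, rc[2] + 1] <- FALSE
  mi <- maze_config(pres, c(0, 0))
  expect_length(adjacent_states(mi, rc_state(2, 2, 5)), 0L)
  expect_error(adjacent_states(mi, rc_state(1, 2, 5)), "not present")
})

test_that("shortest_path matches the breadth-first oracle and handles edge cases", {
  m <- open_maze()
  expect_equal(shortest_path(m, 5, 5)$length, 0L)
  sp <- shortest_path(m, rc_state(0, 0, 10), rc_state(9, 9, 10))
  expect_equal(sp$length, 18L)
  expect_equal(length(sp$path), 19L)
  validate_trajectory(sp$path, m)

  # disconnected components signal unreachable, not an error
  pres <- matrix(TRUE, 4, 4)
  pres[, 3] <- FALSE   # full column wall
  md <- maze_config(pres, c(0, 0))
  expect_true(is.na(shortest_path(md, rc_state(0, 0, 4), rc_state(0, 3, 4))$length))

  # property: lengths equal the BFS oracle on random configurations
  set.seed(11)
  for (i in 1:50) {
    m <- random_maze()
    pm <- maze_matrix(m)
    ok <- which(m$present)
    pts <- sample(ok, 2)
    got <- shortest_path(m, pts[1], pts[2])$length
    want <- bfs_oracle(pm, state_rc(pts[1], 10), state_rc(pts[2], 10))
    expect_equal(got, want)
    if (!is.na(got)) {
      p <- shortest_path(m, pts[1], pts[2])$path
      validate_trajectory(p, m)
      expect_equal(length(p) - 1L, got)
    }
  }
})

test_that("tortuosity is path length over Euclidean distance", {
  m <- open_maze()
  # same row, 3 modules apart, clear path
  expect_equal(tortuosity(m, rc_state(2, 1, 10), rc_state(2, 4, 10)), 1.0)
  # open maze corner to corner
  expect_equal(tortuosity(m, rc_state(0, 0, 10), rc_state(9, 9, 10)),
               sqrt(2), tolerance = 1e-12)
  # forced detour: 5 steps for Euclidean distance 3
  dm <- detour_maze()
  expect_equal(tortuosity(dm, rc_state(0, 0, 4), dm$goal), 5 / 3)
  expect_error(tortuosity(m, m$goal, m$goal), "undefined")
  pres <- matrix(TRUE, 4, 4); pres[, 3] <- FALSE
  md <- maze_config(pres, c(0, 0))
  expect_error(tortuosity(md, rc_state(0, 3, 4), md$goal), "unreachable")
})

test_that("schedules validate starts and conserve trial counts", {
  m1 <- open_maze(4, 4, c(0, 0))
  m2 <- detour_maze()
  m2b <- maze_config(maze_matrix(m2), c(0, 0))  # align goals
  sch <- make_schedule(list(m1, m2b), list(c(6L, 11L, 16L), c(5L, 9L)))
  expect_equal(n_trials(sch), 5L)
  expect_equal(sch$trials_per_config, c(3L, 2L))

  sch1 <- make_schedule(list(m1), list(16L))
  expect_equal(n_trials(sch1), 1L)

  # start on a removed module
  expect_error(make_schedule(list(m2b), list(rc_state(0, 1, 4))), "removed")
  # start on the goal
  expect_error(make_schedule(list(m1), list(m1$goal)), "goal")
  # mismatched goals across configurations
  expect_error(make_schedule(list(m1, open_maze(4, 4, c(3, 3))),
                             list(5L, 5L)), "same goal")
})

test_that("schedule files round-trip", {
  dir <- withr::local_tempdir()
  sch <- mini_schedule()
  idx <- write_schedule(sch, dir)
  sch2 <- read_schedule(idx)
  expect_equal(length(sch2$configs), length(sch$configs))
  for (k in seq_along(sch$configs)) {
    expect_identical(sch2$configs[[k]]$present, sch$configs[[k]]$present)
    expect_identical(sch2$starts[[k]], sch$starts[[k]])
  }
})

test_that("trajectory CSV round-trips through the readers", {
  sch <- mini_schedule()
  gt <- ground_truth("SR", 0.2, 0.8, beta = 5, seed = 3)
  sub <- generate_subject(gt, sch, step_cap = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(sub, path, nc = 6)
  back <- read_trajectories(path, schedule = sch)
  expect_length(back, 1L)
  sub2 <- back[[1L]]
  for (k in seq_along(sub$trials)) {
    for (t in seq_along(sub$trials[[k]])) {
      expect_identical(sub2$trials[[k]][[t]]$states, sub$trials[[k]][[t]]$states)
    }
  }
})

test_that("discretisation maps positions to module-entry sequences", {
  m <- open_maze(4, 4, c(3, 3))
  # samples within one module
  tr <- discretize_trajectory(cbind(c(0.2, 0.5, 0.8), c(0.3, 0.4, 0.2)), m)
  expect_identical(tr$states, rc_state(0, 0, 4))
  # straight line crossing 3 modules
  tr <- discretize_trajectory(cbind(c(0.5, 2.5), c(0.5, 0.5)), m)
  expect_identical(tr$states, rc_state(c(0, 0, 0), 0:2, 4))
  # re-entering a module keeps both visits
  xs <- c(0.5, 1.5, 0.5)
  tr <- discretize_trajectory(cbind(xs, rep(0.5, 3)), m)
  expect_identical(tr$states, rc_state(c(0, 0, 0), c(0, 1, 0), 4))
  # diagonal crossing splits into two orthogonal steps; exact corner tie
  # resolves row-first
  tr <- discretize_trajectory(cbind(c(0.5, 1.5), c(0.5, 1.5)), m)
  expect_identical(tr$states,
                   c(rc_state(0, 0, 4), rc_state(1, 0, 4), rc_state(1, 1, 4)))
  # diagonal crossing that touches the column boundary first goes col-first
  tr <- discretize_trajectory(cbind(c(0.9, 1.6), c(0.5, 1.4)), m)
  expect_identical(tr$states,
                   c(rc_state(0, 0, 4), rc_state(0, 1, 4), rc_state(1, 1, 4)))
  expect_error(discretize_trajectory(cbind(5, 1), m), "outside")
})

test_that("A* lengths agree with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(19)
  for (i in 1:5) {
    m <- random_maze()
    present <- which(m$present)
    edges <- do.call(rbind, lapply(present, function(s) {
      nb <- adjacent_states(m, s)
      nb <- nb[nb > s]
      if (length(nb)) cbind(from = rep(s, length(nb)), to = nb) else NULL
    }))
    g <- igraph::graph_from_edgelist(apply(edges, 2, as.character), directed = FALSE)
    pts <- sample(unique(as.integer(edges)), 2)
    want <- igraph::distances(g, as.character(pts[1]), as.character(pts[2]))[1, 1]
    got <- shortest_path(m, pts[1], pts[2])$length
    expect_equal(if (is.na(got)) Inf else as.numeric(got), want)
  }
})
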