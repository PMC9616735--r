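# Occupancy, optimality, goal rates, diffusivity, Mahalanobis, minimum
# path-distance similarity, difficulty rankings, paired t.

test_that("occupancy maps are proportions of time per state", {
  expect_equal(occupancy_map(c(1L, 2L), 4)[1:2], c(0.5, 0.5))
  m <- occupancy_map(list(c(1L, 2L, 1L), c(3L, 1L)), 4)
  expect_equal(sum(m), 1)
  expect_equal(m[1L], 3 / 5)   # revisits accumulate
  expect_error(occupancy_map(list(), 4), "at least one")
})

test_that("occupancy correlation is Pearson over per-state proportions", {
  a <- occupancy_map(c(1L, 1L, 2L), 4)
  expect_equal(occupancy_correlation(a, a), 1)
  # disjoint support concentrated on 2 states each -> negative correlation
  b <- occupancy_map(c(3L, 4L, 3L), 4)
  expect_lt(occupancy_correlation(a, b), 0)
  # consistent permutation leaves the correlation unchanged
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(occupancy_correlation(a[perm], b[perm]),
               occupancy_correlation(a, b))
  expect_error(occupancy_correlation(rep(0.25, 4), a), "zero-variance")
})

test_that("deviation from optimal counts extra module visitations", {
  m <- open_maze(4, 4, c(3, 3))
  opt <- shortest_path(m, 1L, m$goal)$path
  expect_equal(deviation_from_optimal(opt, m)$extra, 0L)
  # a 2-step backtrack loop adds 2 visitations
  detour <- c(opt[1:3], opt[2], opt[3], opt[4:length(opt)])
  validate_trajectory(detour, m)
  expect_equal(deviation_from_optimal(detour, m)$extra, 2L)
  not_reached <- opt[-length(opt)]
  res <- deviation_from_optimal(not_reached, m)
  expect_true(is.na(res$extra))
  expect_false(res$reached)
})

test_that("goal rate is the mean of goal-reached flags", {
  expect_equal(goal_rate(c(TRUE, TRUE)), 1)
  expect_equal(goal_rate(c(FALSE, FALSE)), 0)
  expect_equal(goal_rate(rep(c(TRUE, FALSE), c(3, 7))), 0.3)
  expect_error(goal_rate(logical(0)), "empty")
})

test_that("diffusivity features follow the stated definitions", {
  # straight 5-step eastward path
  f <- diffusivity_features(rc_state(rep(2, 6), 0:5, 10), nc = 10)
  expect_equal(unname(f), c(25 / 20, 0, 1))
  # closed loop: zero net displacement
  loop <- rc_state(c(0, 0, 1, 1, 0), c(0, 1, 1, 0, 0), 10)
  expect_equal(unname(diffusivity_features(loop, nc = 10)["D_lin"]), 0)
  # exact cancellation leaves the heading undefined
  back_forth <- rc_state(c(0, 0, 0), c(0, 1, 0), 10)
  f2 <- diffusivity_features(back_forth, nc = 10)
  expect_true(is.na(f2["sin_phi"]) && is.na(f2["cos_phi"]))
  # northward movement has positive sine (row 0 is the cue side, i.e. north)
  north <- rc_state(c(5, 4, 3), c(2, 2, 2), 10)
  expect_equal(unname(diffusivity_features(north, nc = 10)[c("sin_phi", "cos_phi")]),
               c(1, 0))
  expect_error(diffusivity_features(1L, nc = 10), "zero-step")
})

test_that("Mahalanobis dissimilarity uses the cluster covariance", {
  set.seed(31)
  cl <- matrix(rnorm(300), ncol = 3)
  mu <- colMeans(cl)
  expect_equal(mahalanobis_dissimilarity(mu, cl), 0)
  # identity-covariance cluster: distance ~ Euclidean
  cl_id <- matrix(rnorm(6000), ncol = 2)
  cl_id <- scale(cl_id)               # exact unit variance, zero mean
  cl_id <- cl_id %*% solve(chol(stats::cov(cl_id)))  # exact identity covariance
  x <- c(2, -1)
  expect_equal(mahalanobis_dissimilarity(x, cl_id),
               sqrt(sum((x - colMeans(cl_id))^2)), tolerance = 1e-8)
  # affine invariance: invertible rescaling of point and cluster together
  A <- matrix(c(2, 0.5, -1, 3, 0, 1, 4, -2, 1), 3)
  b <- c(1, -2, 0.5)
  x3 <- c(0.3, -0.7, 1.2)
  d1 <- mahalanobis_dissimilarity(x3, cl)
  cl_t <- t(A %*% t(cl) + b)
  d2 <- mahalanobis_dissimilarity(as.numeric(A %*% x3 + b), cl_t)
  expect_equal(d1, d2, tolerance = 1e-8)
  expect_error(mahalanobis_dissimilarity(c(0, 0, 0), cl[1:3, ]), "more replicates")
})

test_that("minimum path-distance similarity measures route closeness", {
  m <- open_maze(4, 4, c(3, 3))
  ref <- shortest_path(m, 1L, m$goal)$path
  # identical trajectory -> 0
  expect_equal(as.numeric(min_path_distance_similarity(ref, list(ref), m)), 0)
  # agent parked at the reference start: mean BFS distance from each
  # reference state to that start
  d <- vapply(ref, function(s)
    bfs_oracle(maze_matrix(m), state_rc(s, 4), state_rc(ref[1L], 4)),
    integer(1))
  got <- min_path_distance_similarity(ref, list(ref[1L]), m)
  expect_equal(as.numeric(got), mean(d))
  # adding states to the agent trajectory never increases the measure
  set.seed(33)
  for (i in 1:10) {
    states <- sample(which(m$present), 5)
    bigger <- c(states, sample(which(m$present), 3))
    expect_lte(as.numeric(min_path_distance_similarity(ref, list(bigger), m)),
               as.numeric(min_path_distance_similarity(ref, list(states), m)))
  }
  # disconnected reference states are capped at diameter + 1
  pres <- matrix(TRUE, 4, 4)
  pres[, 3] <- FALSE
  md <- maze_config(pres, c(0, 0))
  ref2 <- c(rc_state(0, 0, 4), rc_state(1, 0, 4))
  island <- rc_state(0, 3, 4)
  got2 <- min_path_distance_similarity(ref2, list(island), md)
  expect_equal(as.numeric(got2), maze_diameter(md) + 1)
  expect_equal(attr(got2, "capped"), 2L)
})

test_that("difficulty rankings use tie-averaged Spearman and Fisher z", {
  x <- c(0.1, 0.5, 0.9, 0.7)
  res <- difficulty_rankings(x, list(same = x, rev = 1 - x))
  expect_equal(res$rho[res$kind == "same"], 1)
  expect_equal(res$rho[res$kind == "rev"], -1)
  res2 <- difficulty_rankings(c(0.2, 0.4, 0.6), list(a = c(0.3, 0.5, 0.4)))
  expect_equal(res2$z, atanh(res2$rho))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_warning(difficulty_rankings(c(0.5, 0.5, 0.5), list(a = c(1, 2, 3))),
                 "constant")
  expect_error(difficulty_rankings(c(1, 2), list(a = c(1, 2))), "at least 3")
})

test_that("paired t matches the textbook statistic", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  res <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(is.infinite(res$t) && res$t > 0)
  a <- c(5.1, 4.8, 6.0, 5.5)
  b <- c(4.9, 4.2, 5.1, 5.6)
  got <- paired_t(a, b)
  want <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$dof, unname(want$parameter))
})
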