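# Agent initialization, learning rules, planning, and choice rules.

test_that("optimal-policy initialization gives gamma^d values for all kinds", {
  m <- open_maze()
  d <- distance_map(m, m$goal)

  mf <- initialize_agent(agent_params("MF", gamma = 0.9), m)
  # an action entering the goal has value exactly 1
  nb <- adjacent_states(m, m$goal)
  for (s in nb) {
    a <- which(m$nbr[, s] == m$goal)
    expect_equal(mf$Q[s, a], 1)
  }

  sr <- initialize_agent(agent_params("SR", gamma = 0.9), m)
  s2 <- which(d == 2L)[1L]
  expect_equal(sr$M[s2, m$goal], 0.81, tolerance = 1e-10)
  expect_equal(sr$M[m$goal, ], replace(numeric(100), m$goal, 1))
  # V(s) = gamma^d(s) everywhere
  expect_equal(sr$M[, m$goal], 0.9^d, tolerance = 1e-10)

  mb <- initialize_agent(agent_params("MB", gamma = 0.9), m)
  expect_true(all(mb$chi))

  expect_error(initialize_agent(agent_params("MF"), detour_maze()), "open maze")
})

test_that("greedy rollouts from sampled starts are shortest-path optimal", {
  m <- open_maze()
  d <- distance_map(m, m$goal)
  set.seed(5)
  starts <- sample(setdiff(which(m$present), m$goal), 12)
  for (kind in c("MF", "MB", "SR")) {
    a <- initialize_agent(agent_params(kind, gamma = 0.9), m)
    for (s0 in starts) {
      s <- s0
      steps <- 0L
      while (s != m$goal && steps <= 30L) {
        cand <- adjacent_states(m, s)
        v <- action_values(a, s, cand, m)
        s <- cand[which.max(v)]
        steps <- steps + 1L
      }
      expect_equal(steps, d[s0], info = paste(kind, "from", s0))
    }
  }
})

test_that("action_values follow each kind's decision rule", {
  m <- open_maze()
  # MB planning through an accurate model: candidate adjacent to goal -> gamma^1
  mb <- initialize_agent(agent_params("MB", gamma = 0.9), m)
  nb <- adjacent_states(m, m$goal)
  two_away <- setdiff(adjacent_states(m, nb[1L]), m$goal)[1L]
  v <- action_values(mb, two_away, c(nb[1L]), m)
  expect_equal(v, 0.9)
  # MB whose model disconnects a candidate values it 0
  mb2 <- mb
  cut_nbrs <- lattice_neighbors(10, 10)[, nb[1L]]
  cut_nbrs <- cut_nbrs[!is.na(cut_nbrs)]
  mb2$chi[cut_nbrs] <- FALSE
  mb2$chi_version <- mb2$chi_version + 1L
  expect_equal(action_values(mb2, two_away, c(nb[1L]), m), 0)
  # SR with alpha = 0 keeps initialized values after any experience
  sr <- initialize_agent(agent_params("SR", alpha = 0, gamma = 0.9), m)
  M0 <- sr$M
  sr <- agent_step_update(sr, m, 1L, 2L)
  expect_identical(sr$M, M0)
  expect_error(action_values(mb, 1L, integer(0), m), "empty")
})

test_that("model-free TD(lambda) update follows the stated order", {
  m <- open4()
  p0 <- agent_params("MF", alpha = 0, gamma = 0.9)
  a0 <- initialize_agent(p0, m)
  Q0 <- a0$Q
  a0 <- agent_step_update(a0, m, 1L, 2L)
  expect_identical(a0$Q, Q0)

  # fresh trial, Q = 0, transition into goal, alpha = 0.5
  p <- agent_params("MF", alpha = 0.5, gamma = 0.9)
  a <- initialize_agent(p, m)
  a$Q[] <- 0
  from <- adjacent_states(m, m$goal)[1L]
  a <- agent_step_update(a, m, from, m$goal)
  expect_equal(sum(a$Q != 0), 1L)
  expect_equal(max(a$Q), 0.5)

  # two-step trial: the step-1 pair receives the step-2 TD error scaled by
  # lambda * gamma = 0.45
  a <- initialize_agent(p, m)
  a$Q[] <- 0
  s1 <- rc_state(3, 1, 4)   # two steps from the corner goal at (3,3)
  s2 <- rc_state(3, 2, 4)
  a <- reset_eligibility(a)
  a <- agent_step_update(a, m, s1, s2)   # TD error 0, no change
  expect_true(all(a$Q == 0))
  a <- agent_step_update(a, m, s2, m$goal)
  act1 <- which(m$nbr[, s1] == s2)
  act2 <- which(m$nbr[, s2] == m$goal)
  expect_equal(a$Q[s2, act2], 0.5)
  expect_equal(a$Q[s1, act1], 0.5 * 0.45)
  expect_equal(sum(a$Q != 0), 2L)
})

test_that("successor TD(lambda) update follows the stated order", {
  m <- open4()
  # alpha = 0 leaves M unchanged (covered above); hand example:
  # M = I, fresh trace, s -> s' (not goal), alpha = 1, gamma = 0.5
  p <- agent_params("SR", alpha = 1, gamma = 0.5)
  a <- initialize_agent(p, m)
  a$M <- diag(16)
  s <- 1L
  sp <- 2L
  a <- reset_eligibility(a)
  a <- agent_step_update(a, m, s, sp)
  want <- diag(16)
  want[s, sp] <- 0.5
  expect_equal(a$M, want)

  # transition into the goal uses the pinned one-hot goal row
  a <- initialize_agent(p, m)
  a$M <- diag(16)
  from <- adjacent_states(m, m$goal)[1L]
  a <- reset_eligibility(a)
  a <- agent_step_update(a, m, from, m$goal)
  expect_equal(a$M[from, m$goal], 0.5)
  expect_equal(a$M[m$goal, ], replace(numeric(16), m$goal, 1))
})

test_that("the binary module model updates only observed entries", {
  m10 <- open_maze()
  a <- initialize_agent(agent_params("MB"), m10)
  # neighbour observed missing
  pres <- matrix(TRUE, 10, 10)
  pres[5, 6] <- FALSE   # (4, 5) removed
  mz <- maze_config(pres, c(2, 7))
  s <- rc_state(5, 5, 10)
  a <- observe_state(a, s, mz)
  expect_false(a$chi[rc_state(4, 5, 10)])
  # far module untouched
  expect_true(a$chi[rc_state(9, 9, 10)])
  # flips back when observed present again
  a <- observe_state(a, s, m10)
  expect_true(a$chi[rc_state(4, 5, 10)])
  # non-adjacent observation is an error
  expect_error(update_model(a, s, rc_state(9, 9, 10), TRUE), "not adjacent")
})

test_that("eligibility reset zeroes traces, preserves learning, idempotent", {
  m <- open4()
  a <- initialize_agent(agent_params("MF", alpha = 0.3, gamma = 0.9), m)
  a <- agent_step_update(a, m, 1L, 2L)
  Q_before <- a$Q
  a1 <- reset_eligibility(a)
  expect_true(all(a1$e_sa == 0))
  expect_identical(a1$Q, Q_before)
  expect_identical(reset_eligibility(a1), a1)

  s <- initialize_agent(agent_params("SR", alpha = 0.3, gamma = 0.9), m)
  s <- agent_step_update(s, m, 1L, 2L)
  expect_true(any(s$e_s != 0))
  expect_true(all(reset_eligibility(s)$e_s == 0))
})

test_that("choice distributions are valid, tie-aware, permutation-equivariant", {
  expect_equal(choice_distribution(c(1, 0), "egreedy", epsilon = 0), c(1, 0))
  expect_equal(choice_distribution(c(0.2, 0.9, 0.1, 0.4), "egreedy", epsilon = 0.1),
               c(0.025, 0.925, 0.025, 0.025))
  expect_equal(choice_distribution(c(0.5, 0.5, 0.5), "softmax", beta = 7),
               rep(1 / 3, 3))
  expect_equal(choice_distribution(c(1, 0), "softmax", beta = 1),
               c(exp(1), 1) / (1 + exp(1)), tolerance = 1e-12)
  # two tied maxima split the greedy mass
  expect_equal(choice_distribution(c(1, 1, 0), "egreedy", epsilon = 0.3),
               c(0.35 + 0.1, 0.35 + 0.1, 0.1))
  set.seed(9)
  for (i in 1:20) {
    v <- stats::runif(sample(2:6, 1))
    perm <- sample(length(v))
    for (pol in c("softmax", "egreedy")) {
      p <- choice_distribution(v, pol, beta = 2, epsilon = 0.2)
      expect_equal(sum(p), 1)
      expect_equal(choice_distribution(v[perm], pol, beta = 2, epsilon = 0.2),
                   p[perm])
    }
  }
})

test_that("closed-form successor matrix matches the discounted series", {
  expect_equal(sr_closed_form(matrix(c(0, 1, 0, 0), 2, byrow = TRUE), 0),
               diag(2))
  # 2-state chain s -> goal with the goal row zeroed (episodic truncation)
  T2 <- matrix(c(0, 1, 0, 0), 2, byrow = TRUE)
  M <- sr_closed_form(T2, 0.5)
  expect_equal(M[1, 2], 0.5)
  expect_equal(M[1, 1], 1)
  # series truncation at 50 terms agrees with the inverse on a random
  # 10-state substochastic T (termination mass makes the tail negligible)
  set.seed(13)
  T10 <- matrix(stats::runif(100), 10)
  T10 <- 0.5 * T10 / rowSums(T10)
  M <- sr_closed_form(T10, 0.9)
  S <- diag(10)
  P <- diag(10)
  for (t in 1:50) {
    P <- P %*% (0.9 * T10)
    S <- S + P
  }
  expect_lt(max(abs(M - S)), 1e-6)
})
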