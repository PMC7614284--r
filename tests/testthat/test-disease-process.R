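test_that("intensity matrix has the illness-death structure", {
  Q <- intensity_matrix(0.1, 0.2, 0.05)
  expect_equal(unname(Q[1, ]), c(-0.1, 0.1, 0))
  expect_equal(unname(Q[2, ]), c(0.05, -0.25, 0.2))
  expect_equal(unname(Q[3, ]), c(0, 0, 0))
  expect_equal(unname(rowSums(Q)), c(0, 0, 0))
  expect_equal(intensity_matrix(0, 0, 0), intensity_matrix(0, 0, 0) * 0,
               ignore_attr = TRUE)
  expect_error(intensity_matrix(-0.1, 0, 0), "rate 'i'")
  expect_error(intensity_matrix(0.1, Inf, 0), "rate 'f'")
})

test_that("annual transition probabilities solve the process exactly", {
  expect_equal(annual_transition_probs(0, 0, 0), diag(3),
               ignore_attr = TRUE)
  P <- annual_transition_probs(0.1, 0, 0)
  expect_equal(P[1, 1], exp(-0.1), tolerance = 1e-12)
  expect_equal(P[1, 2], 1 - exp(-0.1), tolerance = 1e-12)
  expect_equal(P[1, 3], 0)
  # oracle: high-accuracy integration of dP/dt = P Q from the identity
  ode_P <- function(i, f, r) {
    Q <- intensity_matrix(i, f, r)
    deriv <- function(t, y, parms) list(as.vector(matrix(y, 3) %*% Q))
    out <- deSolve::lsoda(as.vector(diag(3)), c(0, 1), deriv, NULL,
                          rtol = 1e-12, atol = 1e-12)
    matrix(out[2, -1], 3)
  }
  expect_equal(unclass(annual_transition_probs(0.1, 0.2, 0.05)),
               ode_P(0.1, 0.2, 0.05), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("matrix-exponential solution matches the ODE oracle on a rate grid", {
  skip_if_not_installed("deSolve")
  grid <- seq(0, 2, length.out = 4)
  worst <- 0
  for (i in grid) for (f in grid) for (r in grid) {
    Q <- matrix(c(-i, i, 0, r, -(r + f), f, 0, 0, 0), 3, byrow = TRUE)
    deriv <- function(t, y, parms) list(as.vector(matrix(y, 3) %*% Q))
    out <- deSolve::lsoda(as.vector(diag(3)), c(0, 1), deriv, NULL,
                          rtol = 1e-11, atol = 1e-11)
    P_ode <- matrix(out[2, -1], 3)
    P <- unclass(annual_transition_probs(i, f, r))
    dimnames(P) <- NULL
    worst <- max(worst, max(abs(P - P_ode)))
  }
  expect_lt(worst, 1e-8)
})

test_that("transition matrices are row-stochastic over a wide rate grid", {
  set.seed(1)
  i <- runif(500, 0, 2); f <- runif(500, 0, 2); r <- runif(500, 0, 2)
  P <- chronicrates:::transition_prob_array(i, f, r)
  sums <- apply(P, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(P[, 3, 1] == 0 & P[, 3, 2] == 0 & P[, 3, 3] == 1))
})

test_that("death probabilities are nondecreasing in case fatality", {
  fgrid <- seq(0, 2, length.out = 30)
  for (i in c(0.05, 0.5)) for (r in c(0, 0.3)) {
    P13 <- vapply(fgrid, function(f) annual_transition_probs(i, f, r)[1, 3], 0)
    P23 <- vapply(fgrid, function(f) annual_transition_probs(i, f, r)[2, 3], 0)
    expect_true(all(diff(P13) >= -1e-12))
    expect_true(all(diff(P23) >= -1e-12))
  }
})

test_that("state occupancy follows the recursion and conserves probability", {
  A <- 50
  rs0 <- rate_schedule(rep(0, A + 1), rep(0, A + 1))
  S <- state_occupancy(rs0)
  expect_true(all(S[, 1] == 1))
  rs <- demo_rates(A)
  S <- state_occupancy(rs)
  expect_lt(max(abs(rowSums(S) - 1)), 1e-10)
  # constant rates: occupancy equals S0 times the matrix power of one P
  rs_c <- rate_schedule(rep(0.01, A + 1), rep(0.1, A + 1))
  S_c <- state_occupancy(rs_c)
  P1 <- annual_transition_probs(0.01, 0.1, 0)
  s <- c(1, 0, 0)
  for (a in 1:A) s <- as.vector(s %*% P1)
  expect_equal(unname(S_c[A + 1, ]), s, tolerance = 1e-12)
  expect_error(state_occupancy(rs, S0 = c(0.5, 0.2, 0.2)),
               "probability vector")
})

test_that("prevalence and mortality probability follow their definitions", {
  expect_equal(prevalence(c(0.5, 0.5, 0)), 0.5)
  expect_equal(prevalence(c(1, 0, 0)), 0)
  expect_equal(prevalence(c(0.2, 0.3, 0.5)), 0.6)
  expect_error(prevalence(c(0, 0, 1)), "alive")
  P <- annual_transition_probs(0.1, 0.3, 0)
  expect_equal(mortality_prob(P, 1), P[2, 3])
  expect_equal(mortality_prob(P, 0), P[1, 3])
  P2 <- matrix(0, 3, 3); P2[1, 3] <- 0.01; P2[2, 3] <- 0.2
  expect_equal(mortality_prob(P2, 0.5), 0.105)
  expect_error(mortality_prob(P, 1.5), "probability")
})

test_that("outcome probabilities compose the independently tested pieces", {
  rs <- demo_rates(60)
  out <- outcome_probabilities(rs)
  expect_true(all(as.matrix(out[-1]) >= 0 & as.matrix(out[-1]) <= 1))
  P <- chronicrates:::transition_prob_array(rs$i, rs$f, rs$r)
  S <- state_occupancy(rs)
  for (a in c(0, 10, 30, 60)) {
    expect_equal(out$inc_prob[a + 1], 1 - P[a + 1, 1, 1])
    expect_equal(out$prev[a + 1], prevalence(S[a + 1, ]))
    expect_equal(out$mort_prob[a + 1],
                 mortality_prob(P[a + 1, , ], out$prev[a + 1]))
    expect_equal(out$rem_prob[a + 1], P[a + 1, 2, 1])
  }
  # all-zero rates: nothing ever happens
  rs0 <- rate_schedule(rep(0, 61), rep(0, 61))
  out0 <- outcome_probabilities(rs0)
  expect_true(all(as.matrix(out0[-1]) == 0))
  # no remission: remission probability identically 0
  rs_nr <- rate_schedule(rs$i, rs$f)
  expect_true(all(outcome_probabilities(rs_nr)$rem_prob == 0))
})

test_that("prevalence is carried forward when the cohort dies out numerically", {
  A <- 100
  rs <- rate_schedule(i = rep(10, A + 1), f = rep(50, A + 1))
  expect_message(out <- outcome_probabilities(rs), "carried")
  carried <- attr(out, "carried")
  expect_gt(length(carried), 0)
  expect_true(all(is.finite(out$prev)))
  last_ok <- min(carried) - 1
  expect_true(all(out$prev[out$age >= last_ok] == out$prev[last_ok + 1]))
})
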