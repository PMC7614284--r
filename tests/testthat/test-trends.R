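test_that("trend matrices validate, fill and interpolate on the log scale", {
  A <- 10
  # supply only years 0 and 50: earliest carried back, gaps log-interpolated
  vals <- cbind(rep(4, A + 1), rep(2, A + 1))
  tm <- trend_matrix(vals, years = c(10, 50), A = A)
  expect_equal(dim(tm), c(A + 1, 101))
  expect_true(all(tm[, 101] == 1))
  expect_equal(tm[1, 1], 4)                       # carried backward
  expect_equal(tm[1, 31], exp(mean(log(c(4, 2)))), tolerance = 1e-12)
  expect_equal(tm[1, 76], exp(mean(log(c(2, 1)))), tolerance = 1e-12)
  expect_error(trend_matrix(cbind(rep(-1, A + 1)), years = 0, A = A),
               "positive")
  expect_error(trend_matrix(cbind(rep(2, A + 1)), years = 100, A = A),
               "equal 1")
  expect_error(trend_matrix(vals[1:5, ], years = c(10, 50), A = A),
               "age rows")
})

test_that("trend matrices round-trip through CSV", {
  A <- 8
  set.seed(3)
  vals <- matrix(exp(rnorm((A + 1) * 101, 0, 0.1)), A + 1, 101)
  vals[, 101] <- 1
  tm <- trend_matrix(vals, 0:100, A = A)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(age = 0:A, as.data.frame(unclass(tm))), path,
                   row.names = FALSE)
  tm2 <- read_trend_matrix(path, A = A)
  expect_equal(unclass(tm2), unclass(tm), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cohort pathway reduces exactly to the no-trend pathway", {
  rs <- demo_rates(100)
  one <- trend_matrix(matrix(1, 101, 101), 0:100)
  a <- outcome_probabilities(rs)
  b <- cohort_outcome_probabilities(rs, one, one)
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-12)
})

test_that("age 0 is untouched by trends in past incidence", {
  rs <- demo_rates(50)
  vals <- matrix(2, 51, 101); vals[, 101] <- 1
  tm <- trend_matrix(vals, 0:100, A = 50)
  a <- outcome_probabilities(rs)
  b <- cohort_outcome_probabilities(rs, trend_i = tm)
  expect_equal(unlist(b[1, -1]), unlist(a[1, -1]), tolerance = 1e-14)
})

test_that("cohort pathway matches an explicit per-cohort oracle", {
  A <- 20
  rs <- rate_schedule(rep(0.02, A + 1), rep(0.1, A + 1), rep(0.01, A + 1))
  set.seed(4)
  mk <- function() {
    v <- matrix(exp(rnorm((A + 1) * 101, 0, 0.2)), A + 1, 101)
    v[, 101] <- 1
    trend_matrix(v, 0:100, A = A)
  }
  ti <- mk(); tf <- mk()
  got <- cohort_outcome_probabilities(rs, ti, tf)
  prev_or <- numeric(A + 1)
  for (a in 0:A) {
    s <- c(1, 0, 0)
    if (a > 0) for (b in 0:(a - 1)) {
      y <- 100 - a + b
      P <- annual_transition_probs(rs$i[b + 1] * ti[b + 1, y + 1],
                                   rs$f[b + 1] * tf[b + 1, y + 1],
                                   rs$r[b + 1])
      s <- as.vector(s %*% P)
    }
    prev_or[a + 1] <- s[2] / (s[1] + s[2])
  }
  expect_equal(got$prev, prev_or, tolerance = 1e-12)
  expect_error(cohort_outcome_probabilities(demo_rates(40), ti, tf),
               "fewer ages")
})
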