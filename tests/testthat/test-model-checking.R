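test_that("conflict p-value follows the Beta tail construction", {
  # symmetric case: Beta(5.5, 5.5) has median 0.5, so q = 0.5, p = 1
  res <- conflict_pvalue(5, 10, rep(0.5, 100))
  expect_equal(res$q, 0.5)
  expect_equal(res$p_value, 1)
  # zero successes against a synthesis at 0.5: oracle is the Beta CDF
  res0 <- conflict_pvalue(0, 10, rep(0.5, 100))
  q_oracle <- pbeta(0.5, 0.5, 10.5)
  expect_equal(res0$q, q_oracle)
  expect_equal(res0$p_value, 2 * min(q_oracle, 1 - q_oracle))
  expect_lt(res0$p_value, 0.01)
  # no data reduces to the Beta(0.5, 0.5) prior
  resn <- conflict_pvalue(0, 0, rep(0.3, 100))
  expect_equal(resn$q, pbeta(0.3, 0.5, 0.5))
  # Rao-Blackwellised averaging over draws
  set.seed(1)
  draws <- runif(500, 0.2, 0.8)
  expect_equal(conflict_pvalue(5, 10, draws)$q,
               mean(pbeta(draws, 5.5, 5.5)))
  expect_error(conflict_pvalue(5, 10, numeric(0)), "empty")
  expect_error(conflict_pvalue(5, 10, c(0.5, 1.5)), "0, 1")
  expect_error(conflict_pvalue(11, 10, 0.5), "y <= n")
})

test_that("LOO elpd handles degenerate and standard cases", {
  # a single draw: elpd is that draw's pointwise log-likelihood
  ll1 <- matrix(c(-1.2, -3.4, -0.5), 1)
  res1 <- loo_elpd(ll1)
  expect_equal(res1$pointwise$elpd, as.vector(ll1))
  expect_equal(res1$elpd, sum(ll1))
  # identical draws: plain log predictive density, flagged
  llc <- matrix(rep(c(-1, -2), each = 50), 50)
  expect_message(resc <- loo_elpd(llc), "degenerate")
  expect_equal(resc$pointwise$elpd, c(-1, -2))
  expect_true(all(resc$pointwise$degenerate))
  # total is the sum of the pointwise values, order-invariant
  set.seed(2)
  ll <- matrix(rnorm(400 * 30, -2, 0.3), 400)
  res <- loo_elpd(ll)
  expect_equal(res$elpd, sum(res$pointwise$elpd))
  perm <- sample(30)
  resp <- loo_elpd(ll[, perm])
  expect_equal(resp$elpd, res$elpd, tolerance = 1e-10)
  expect_equal(resp$pointwise$elpd, res$pointwise$elpd[perm])
  expect_error(loo_elpd(matrix(c(1, -Inf), 1)), "finite")
})

test_that("LOO penalises influence: elpd is below the in-sample density", {
  set.seed(3)
  # draws of a binomial probability around the truth; LOO elpd for each
  # observation must not exceed the posterior-averaged log density
  p_draws <- plogis(rnorm(1000, 0, 0.3))
  y <- rbinom(20, 50, 0.5)
  ll <- sapply(y, function(yy) dbinom(yy, 50, p_draws, log = TRUE))
  res <- loo_elpd(ll)
  lpd <- apply(ll, 2, function(c) chronicrates:::logsumexp(c) - log(length(c)))
  expect_true(all(res$pointwise$elpd <= lpd + 1e-8))
})

test_that("fitted-vs-observed tables compare each record with its posterior", {
  fit <- small_fit()
  tab <- fitted_vs_observed(fit)
  expect_equal(nrow(tab), nrow(small_data()))
  expect_true(all(c("observed", "fitted_median", "fitted_lower",
                    "fitted_upper", "fitted_mode", "conflict_p") %in%
                    names(tab)))
  expect_true(all(tab$fitted_lower <= tab$fitted_median + 1e-12))
  expect_true(all(tab$conflict_p > 0 & tab$conflict_p <= 1))
  # most records generated from the model itself should not conflict
  expect_lt(mean(tab$conflict_p < 0.05), 0.12)
  # records with denominator 0 are dropped with a note
  d0 <- rbind(small_data(),
              data.frame(area = "all", gender = "all", age = 0,
                         measure = "rem", num = 0, denom = 0))
  expect_message(tab0 <- fitted_vs_observed(fit, d0), "denominator 0")
  expect_equal(nrow(tab0), nrow(small_data()))
})

test_that("a perfect fit with huge denominators yields p-values near 1", {
  n <- 1e6
  y <- 2e5
  draws <- rep(y / n, 200)
  expect_gt(conflict_pvalue(y, n, draws)$p_value, 0.9)
})
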