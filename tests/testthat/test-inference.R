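test_that("Laplace approximation is exact for a Gaussian posterior", {
  # normal likelihood with normal prior collapses to a quadratic log
  # density; the Laplace fit must reproduce it exactly
  mu <- 1.7; sd <- 0.6
  toy <- list(n_par = 1, par_names = "theta",
              log_post = function(th) dnorm(th, mu, sd, log = TRUE),
              init = 0)
  fit <- fit_mode_laplace(toy, seed = 1, n_draws = 4000)
  expect_equal(unname(fit$mode), mu, tolerance = 1e-5)
  expect_equal(sqrt(fit$vcov[1, 1]), sd, tolerance = 1e-3)
  q <- quantile(fit$draws[, 1], c(0.025, 0.975))
  expect_equal(unname(q), qnorm(c(0.025, 0.975), mu, sd), tolerance = 0.05)
})

test_that("both engines are exactly reproducible under a fixed seed", {
  data <- small_data()
  m <- assemble_model(model_config(A = 60, K = 6), data)
  f1 <- fit_mode_laplace(m, seed = 11, n_draws = 50)
  f2 <- fit_mode_laplace(m, seed = 11, n_draws = 50)
  expect_identical(f1$draws, f2$draws)
  # short chains: convergence warnings are expected and irrelevant here
  s1 <- suppressWarnings(
    sample_posterior(m, chains = 2, iter = 200, warmup = 100, seed = 5))
  s2 <- suppressWarnings(
    sample_posterior(m, chains = 2, iter = 200, warmup = 100, seed = 5))
  expect_identical(s1$draws, s2$draws)
  f3 <- fit_mode_laplace(m, seed = 12, n_draws = 50)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the mode engine recovers truth on a small synthetic fixture", {
  fit <- small_fit()
  truth <- small_truth()[["all:all"]]
  probs <- suppressMessages(outcome_probabilities(truth))
  inform <- which(probs$prev > 0.01)
  s <- fit_summary(fit, "f")
  relerr <- abs(s$median[inform] - truth$f[inform]) / truth$f[inform]
  expect_lt(mean(relerr), 0.15)
  cover <- mean(truth$f[inform] >= s$lower[inform] &
                  truth$f[inform] <= s$upper[inform])
  expect_gt(cover, 0.7)
  # derived rate draws positive, probability draws within [0, 1]
  expect_true(all(fit$gen[["all:all"]]$f > 0))
  expect_true(all(fit$gen[["all:all"]]$prev >= 0 &
                    fit$gen[["all:all"]]$prev <= 1))
})

test_that("sampling with no data recovers the prior", {
  # all denominators zero: the likelihood contributes nothing, so the
  # posterior is the prior (standard normal z-scores, Gamma(2,1) smoothness)
  d0 <- data.frame(age = rep(0:60, 2),
                   measure = rep(c("inc", "mort"), each = 61),
                   num = 0, denom = 0)
  m <- assemble_model(model_config(A = 60, K = 6), d0)
  fit <- suppressWarnings(
    sample_posterior(m, chains = 2, iter = 4000, warmup = 1500, seed = 3))
  z <- fit$draws[, "cf.z1"]
  expect_equal(mean(z), 0, tolerance = 0.15)
  expect_equal(sd(z), 1, tolerance = 0.15)
  lam <- exp(fit$draws[, "cf.loglambda"])
  expect_equal(median(lam), qgamma(0.5, 2, 1), tolerance = 0.25)
})

test_that("sampler reports convergence diagnostics for every parameter", {
  data <- small_data()
  m <- assemble_model(model_config(A = 60, K = 6), data)
  fit <- suppressWarnings(
    sample_posterior(m, chains = 2, iter = 500, warmup = 300, seed = 9))
  expect_equal(nrow(fit$diagnostics), m$n_par)
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_true(all(fit$diagnostics$ess > 0))
  expect_equal(nrow(fit$draws), 2 * 500)
})

test_that("mode-finding is at least an order of magnitude faster than sampling", {
  data <- small_data()
  m <- assemble_model(model_config(A = 60, K = 6), data)
  t_mode <- system.time(
    fit_mode_laplace(m, seed = 2, n_draws = 100))["elapsed"]
  t_samp <- system.time(suppressWarnings(
    sample_posterior(m, chains = 2, iter = 6000, warmup = 2000,
                     seed = 2, max_gen = 100)))["elapsed"]
  expect_gt(unname(t_samp / t_mode), 10)
})

test_that("draws export in long format and round-trip", {
  fit <- small_fit()
  path <- tempfile(fileext = ".csv")
  write_draws(fit, path)
  long <- utils::read.csv(path)
  expect_equal(nrow(long), nrow(fit$draws) * ncol(fit$draws))
  back <- matrix(long$value, ncol = ncol(fit$draws))
  expect_equal(back[, 1], unname(fit$draws[, 1]))
})
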