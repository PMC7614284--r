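test_that("count data validation enforces the schema", {
  d <- data.frame(age = 0:1, measure = c("inc", "prev"), num = c(1, 2),
                  denom = c(10, 10))
  cd <- count_data(d)
  expect_s3_class(cd, "count_data")
  expect_equal(cd$area, c("all", "all"))
  expect_error(count_data(transform(d, measure = c("inc", "bogus"))),
               "row\\(s\\) 2")
  expect_error(count_data(transform(d, num = c(11, 2))), "exceeds")
  expect_error(count_data(rbind(d, d[1, ])), "duplicate")
  expect_error(count_data(transform(d, num = c(1.5, 2))), "integers")
})

test_that("binomial log-likelihood matches closed forms and flags degeneracy", {
  # incidence probability exactly 0.5 when i = log 2, f = r = 0
  rs <- rate_schedule(rep(log(2), 2), rep(0, 2))
  d <- count_data(data.frame(age = 0, measure = "inc", num = 5, denom = 10))
  ll <- log_likelihood(d, rs)
  expect_equal(ll$total, dbinom(5, 10, 0.5, log = TRUE), tolerance = 1e-10)
  expect_equal(ll$total, -1.40204, tolerance = 1e-5)
  # records with denominator zero contribute exactly zero
  d0 <- count_data(data.frame(age = 0:1, measure = "inc", num = c(5, 0),
                              denom = c(10, 0)))
  ll0 <- log_likelihood(d0, rs)
  expect_equal(ll0$pointwise[2], 0)
  expect_equal(ll0$total, ll$total)
  # impossible record: probability 0 with y > 0 flags -Inf, no error
  rs0 <- rate_schedule(rep(0, 2), rep(0, 2))
  d1 <- count_data(data.frame(age = 0, measure = "inc", num = 1, denom = 10))
  expect_message(llbad <- log_likelihood(d1, rs0), "infinite")
  expect_equal(llbad$pointwise[1], -Inf)
  expect_equal(llbad$flagged, 1L)
  # additivity on a full synthetic dataset
  data <- small_data()
  truth <- small_truth()[["all:all"]]
  llf <- log_likelihood(data, truth)
  expect_equal(llf$total, sum(llf$pointwise))
  expect_equal(length(llf$pointwise), nrow(data))
})

test_that("area-SD prior elicitation round-trips fold-ratio judgements", {
  for (pair in list(c(5, 50), c(2, 20), c(3, 8))) {
    p <- elicit_area_sd_prior(pair[1], pair[2])
    expect_equal(p$ratio_at_mean, pair[1], tolerance = 1e-6)
    expect_equal(p$ratio_at_q975, pair[2], tolerance = 1e-6)
    # independent round trip from the returned gamma itself
    expect_equal(exp(2 * 1.959964 * p$shape / p$rate), pair[1],
                 tolerance = 1e-6)
    expect_equal(exp(2 * 1.959964 *
                       qgamma(0.975, p$shape, rate = p$rate)), pair[2],
                 tolerance = 1e-6)
  }
  expect_error(elicit_area_sd_prior(5, 5), "ratio_guess < ratio_upper")
  expect_error(elicit_area_sd_prior(0.5, 5), "ratio_guess")
})

test_that("assembled models have the documented parameter counts", {
  data <- small_data()
  m <- assemble_model(model_config(A = 60, K = 6), data)
  # K coefficients per modelled rate plus one smoothness SD each
  expect_equal(m$n_par, 2 * (6 + 1))
  m2 <- assemble_model(model_config(A = 60, K = 6, remission = "const"),
                       data)
  expect_equal(m2$n_par, 2 * 7 + 1)
  # hierarchical: per-area intercept scores and nonlinear terms, common
  # slope, mean intercept, two scale parameters for case fatality
  schier <- scenario_config("hierarchical", A = 60, seed = 5, n_areas = 3)
  dh <- simulate_dataset(make_true_rates(schier), schier)
  mh <- assemble_model(model_config(A = 60, K = 6, hierarchical = TRUE), dh)
  # incidence: 6 coefficients per area + 1 smoothness SD; case fatality:
  # per-area intercept scores and 4 nonlinear terms, b1, b2, two scale
  # parameters
  expect_equal(mh$n_par, (3 * 6 + 1) + (3 + 3 * 4 + 2 + 2))
  # additive gender: shared area coefficients plus K male offsets per rate
  scg <- scenario_config("gendered", A = 60, seed = 6, n_areas = 1)
  dg <- simulate_dataset(make_true_rates(scg), scg)
  mg <- assemble_model(model_config(A = 60, K = 6, gender = "additive"), dg)
  expect_equal(mg$n_par, 2 * (6 + 1 + 6))
})

test_that("inconsistent configurations are rejected", {
  data <- small_data()
  drem <- rbind(data.frame(area = "all", gender = "all", age = 0,
                           measure = "rem", num = 1, denom = 10), data)
  expect_error(assemble_model(model_config(A = 60), count_data(drem)),
               "remission")
  expect_error(assemble_model(model_config(A = 60, hierarchical = TRUE),
                              data), "single area")
  expect_error(assemble_model(model_config(A = 60, gender = "additive"),
                              data), "two genders")
  scg <- scenario_config("gendered", A = 60, seed = 6, n_areas = 1)
  dg <- simulate_dataset(make_true_rates(scg), scg)
  expect_error(assemble_model(model_config(A = 60), dg),
               "multiple genders")
})

test_that("log posterior is finite at the crude starting values", {
  data <- small_data()
  for (cfg in list(model_config(A = 60, K = 6),
                   model_config(A = 60, K = 6,
                                cf = list(a_base = 30, increasing = TRUE)))) {
    m <- assemble_model(cfg, data)
    th0 <- chronicrates:::model_init(m)
    expect_true(is.finite(model_log_post(m, th0)))
  }
})
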