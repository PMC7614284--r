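# Shared fixtures.  Everything is generated in code; heavier fits are
# memoised so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small single-area scenario for unit tests (A = 60 keeps fits fast)
small_scenario <- function(...) scenario_config("single-area", A = 60,
                                                seed = 42, ...)

small_data <- function() memo("small_data", {
  sc <- small_scenario()
  simulate_dataset(make_true_rates(sc), sc)
})

small_truth <- function() memo("small_truth", {
  make_true_rates(small_scenario())
})

small_fit <- function() memo("small_fit", {
  m <- assemble_model(model_config(A = 60, K = 6), small_data())
  fit_mode_laplace(m, seed = 1, n_draws = 400)
})

# a gentle smooth schedule used in deterministic process tests
demo_rates <- function(A = 100) {
  x <- (0:A) / A
  rate_schedule(i = exp(-9 + 5 * x), f = exp(-5 + 3 * x),
                r = rep(0.02, A + 1))
}
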