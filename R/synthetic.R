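#' Scenario configuration for synthetic datasets
#'
#' Defines the study conditions for simulation experiments: the model
#' variant, the true rate curves, the observation denominators by age and
#' measure, and the seed.  Defaults mimic the scale of national
#' burden-of-disease inputs: populations at risk of the order 5e4 per year
#' of age for incidence and mortality, prevalence survey samples of order
#' 1e3, with denominators decaying above age 90 so that the high-age
#' uncertainty behaviour of real data is exercised.
#'
#' @param variant One of \code{"single-area"}, \code{"hierarchical"},
#'   \code{"gendered"}, \code{"trended"}.
#' @param A Maximum age.
#' @param seed Seed used for every random element of the scenario (area
#'   effects and binomial draws); mandatory.
#' @param n_inc,n_mort,n_prev,n_rem Baseline denominators per year of age
#'   for each measure (\code{n_rem} 0 unless remission data are wanted).
#' @param curves Named list of true log-quadratic curve parameters, each
#'   \code{c(intercept, slope, curvature)} over age scaled to [0, 1]:
#'   \code{inc}, \code{cf}.  Defaults give a chronic-disease shape:
#'   incidence rising from about 2e-4 at age 0 to 2e-2 at age A with the
#'   log curve flattening at old age, case fatality from about 5e-3 to 0.17
#'   steepening with age.
#' @param rem_rate True constant remission rate (0 = no remission).
#' @param n_areas Number of areas (hierarchical variant).
#' @param b1,lambda1 Mean and SD of true area intercepts for case fatality
#'   (hierarchical variant); area intercepts are drawn
#'   Normal(b1, lambda1^2).
#' @param male_effect Additive male offsets on the log scale,
#'   \code{c(inc, cf)} (gendered variant).
#' @param interaction_sd SD of area-specific departures from the common
#'   male effect (0 = purely additive truth).
#' @param a_base,increasing Structural constraints honoured by the truth.
#' @param trend_i,trend_f Trend matrices applied to the truth (trended
#'   variant).
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(variant = c("single-area", "hierarchical",
                                        "gendered", "trended"),
                            A = 100, seed,
                            n_inc = 50000, n_mort = 50000, n_prev = 1000,
                            n_rem = 0,
                            curves = list(inc = c(-8.5, 6.0, -1.5),
                                          cf = c(-5.3, 2.2, 1.3)),
                            rem_rate = 0,
                            n_areas = 3, b1 = -5.1, lambda1 = 0.3,
                            male_effect = c(inc = 0.3, cf = 0.4),
                            interaction_sd = 0,
                            a_base = 0, increasing = FALSE,
                            trend_i = NULL, trend_f = NULL) {
  variant <- match.arg(variant)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  for (n in c(n_inc, n_mort, n_prev, n_rem))
    if (n < 0 || n != round(n)) stop("denominators must be nonnegative ",
                                     "integers", call. = FALSE)
  structure(list(variant = variant, A = as.integer(A),
                 seed = as.integer(seed),
                 n_inc = n_inc, n_mort = n_mort, n_prev = n_prev,
                 n_rem = n_rem, curves = curves, rem_rate = rem_rate,
                 n_areas = n_areas, b1 = b1, lambda1 = lambda1,
                 male_effect = male_effect,
                 interaction_sd = interaction_sd,
                 a_base = a_base, increasing = increasing,
                 trend_i = trend_i, trend_f = trend_f),
            class = "scenario_config")
}

# smooth positive truth curve honouring a_base / increasing; log-quadratic
# in scaled age (deliberately not in the spline family the model fits)
true_curve <- function(pars, A, a_base = 0, increasing = FALSE) {
  x <- pmax(0:A, a_base) / A
  eta <- pars[1] + pars[2] * x + (if (length(pars) > 2) pars[3] else 0) * x^2
  if (!increasing) return(exp(eta))
  # nondecreasing construction: cumulative increments above a_base
  out <- numeric(A + 1)
  at <- 0:A >= a_base
  inc <- exp(eta[at] - log(sum(0:A >= a_base) / 2))
  out[at] <- cumsum(inc)
  out[!at] <- out[which(at)[1]]
  out
}

#' True rate schedules for a scenario
#'
#' @param scenario A \code{\link{scenario_config}}.
#' @return Named list (keyed "area:gender") of \code{\link{rate_schedule}}
#'   objects, with the true parameters attached as attributes
#'   (\code{"area_intercepts"}, \code{"male_effects"}).
#' @export
make_true_rates <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(scenario$seed)
  A <- scenario$A
  cv <- scenario$curves
  base_i <- function(shift = 0) {
    p <- cv$inc; p[1] <- p[1] + shift
    true_curve(p, A, scenario$a_base, FALSE)
  }
  base_f <- function(shift = 0) {
    p <- cv$cf; p[1] <- p[1] + shift
    true_curve(p, A, scenario$a_base, scenario$increasing)
  }
  r <- rep(scenario$rem_rate, A + 1)
  out <- list()
  if (scenario$variant %in% c("single-area", "trended")) {
    out[["all:all"]] <- rate_schedule(base_i(), base_f(), r)
  } else if (scenario$variant == "hierarchical") {
    ints <- stats::rnorm(scenario$n_areas, scenario$b1, scenario$lambda1)
    shift <- ints - scenario$b1
    areas <- sprintf("area%02d", seq_len(scenario$n_areas))
    for (k in seq_along(areas))
      out[[group_key(areas[k], "all")]] <-
        rate_schedule(base_i(), base_f(shift[k]), r)
    attr(out, "area_intercepts") <- stats::setNames(ints, areas)
  } else if (scenario$variant == "gendered") {
    areas <- sprintf("area%02d", seq_len(scenario$n_areas))
    dev_i <- stats::rnorm(scenario$n_areas, 0, scenario$interaction_sd)
    dev_f <- stats::rnorm(scenario$n_areas, 0, scenario$interaction_sd)
    for (k in seq_along(areas)) {
      out[[group_key(areas[k], "female")]] <-
        rate_schedule(base_i(), base_f(), r)
      out[[group_key(areas[k], "male")]] <-
        rate_schedule(base_i(scenario$male_effect[["inc"]] + dev_i[k]),
                      base_f(scenario$male_effect[["cf"]] + dev_f[k]), r)
    }
    attr(out, "male_effects") <-
      list(inc = scenario$male_effect[["inc"]] + dev_i,
           cf = scenario$male_effect[["cf"]] + dev_f)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# denominators by age: flat to age 90, exponential decay beyond
denominator_profile <- function(n0, A) {
  ages <- 0:A
  round(n0 * ifelse(ages <= 90, 1, exp(-0.35 * (ages - 90))))
}

#' Simulate a count dataset from known rates
#'
#' Draws binomial counts for each (group, age, measure) cell from the
#' outcome probabilities implied by the true rates via the multistate
#' process (with the cohort time-trend pathway for trended scenarios).
#'
#' @param truth Named list of \code{\link{rate_schedule}}s, as from
#'   \code{\link{make_true_rates}} (keys "area:gender").
#' @param scenario The \code{\link{scenario_config}} (provides denominators,
#'   trends and the seed).
#' @param seed Override of the scenario seed for replicate datasets.
#' @return A \code{\link{count_data}} data frame.
#' @export
simulate_dataset <- function(truth, scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "scenario_config"))
  set.seed(as.integer(seed))
  A <- scenario$A
  dens <- list(inc = denominator_profile(scenario$n_inc, A),
               mort = denominator_profile(scenario$n_mort, A),
               prev = denominator_profile(scenario$n_prev, A),
               rem = denominator_profile(scenario$n_rem, A))
  rows <- list()
  for (k in names(truth)) {
    ag <- strsplit(k, ":", fixed = TRUE)[[1]]
    probs <- if (scenario$variant == "trended")
      suppressMessages(cohort_outcome_probabilities(
        truth[[k]], scenario$trend_i, scenario$trend_f))
    else suppressMessages(outcome_probabilities(truth[[k]]))
    for (m in c("inc", "prev", "mort", "rem")) {
      n <- dens[[m]]
      if (all(n == 0)) next
      p <- clamp01(probs[[measure_col[[m]]]])
      rows[[length(rows) + 1]] <- data.frame(
        area = ag[1], gender = ag[2], age = 0:A, measure = m,
        num = stats::rbinom(A + 1, n, p), denom = n)
    }
  }
  count_data(do.call(rbind, rows))
}
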