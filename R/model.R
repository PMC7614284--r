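#' Model configuration
#'
#' Collects the structural choices defining a model variant: which rates are
#' spline-modelled with what constraints, whether remission is excluded,
#' constant, or age-varying, whether areas are pooled hierarchically,
#' how gender enters, and any calendar-time trend matrices.
#'
#' @param A Maximum age (integer; ages run 0..A).
#' @param K Number of spline basis terms per age curve.
#' @param cf,inc Lists with elements \code{a_base} (age below which the rate
#'   is constant, default 0) and \code{increasing} (nondecreasing constraint,
#'   default FALSE) for case fatality and incidence.
#' @param remission One of \code{"none"} (remission impossible, r = 0),
#'   \code{"const"} (a single remission rate shared across ages, areas and
#'   genders), or \code{"spline"} (an age curve, still shared across areas
#'   and genders).
#' @param rem Constraint list for the remission age curve (only used when
#'   \code{remission = "spline"}).
#' @param hierarchical Logical; partial pooling of case-fatality intercepts
#'   across areas (random intercepts, common slope).  Incidence always gets
#'   independent coefficients per area.
#' @param gender \code{"none"}, \code{"additive"} (male offsets on the
#'   spline coefficients, shared across areas) or \code{"interaction"}
#'   (independent coefficients per area-gender combination).
#' @param trend_i,trend_f Optional \code{\link{trend_matrix}} objects fixing
#'   past incidence and case-fatality rates relative to the data year.
#' @param priors A \code{\link{prior_set}}.
#' @param fixed Named list of hyperparameters to fix rather than estimate:
#'   any of \code{lambda_cf}, \code{lambda_inc}, \code{lambda_rem} (the
#'   smoothness SDs, e.g. at posterior modes from an optimisation run, to
#'   stabilise sampling), \code{lambda_area}.
#' @return A list of class \code{"model_config"}.
#' @export
model_config <- function(A = 100, K = 10,
                         cf = list(), inc = list(), rem = list(),
                         remission = c("none", "const", "spline"),
                         hierarchical = FALSE,
                         gender = c("none", "additive", "interaction"),
                         trend_i = NULL, trend_f = NULL,
                         priors = prior_set(), fixed = list()) {
  remission <- match.arg(remission)
  gender <- match.arg(gender)
  fill <- function(x) {
    x <- utils::modifyList(list(a_base = 0, increasing = FALSE), x)
    if (x$a_base < 0 || x$a_base > A) stop("a_base must lie in 0..A",
                                           call. = FALSE)
    x
  }
  if (A < 2 || K < 3 || K > A + 1)
    stop("need A >= 2 and 3 <= K <= A + 1", call. = FALSE)
  for (tm in list(trend_i, trend_f))
    if (!is.null(tm) && !inherits(tm, "trend_matrix"))
      stop("trend_i/trend_f must be trend_matrix objects", call. = FALSE)
  stopifnot(inherits(priors, "prior_set"))
  structure(list(A = as.integer(A), K = as.integer(K),
                 cf = fill(cf), inc = fill(inc), rem = fill(rem),
                 remission = remission, hierarchical = hierarchical,
                 gender = gender, trend_i = trend_i, trend_f = trend_f,
                 priors = priors, fixed = fixed),
            class = "model_config")
}

#' Assemble the joint Bayesian model
#'
#' Combines a configuration with a dataset into an engine-agnostic model
#' object exposing the unconstrained parameter layout, log-prior,
#' deterministic parameter-to-rates map, and pointwise log-likelihood.
#' Smoothness standard deviations are sampled on the log scale (with the
#' Jacobian included in the log-prior), so the whole parameter vector is
#' unconstrained.
#'
#' @param config A \code{\link{model_config}}.
#' @param data A \code{\link{count_data}} data frame (or one coercible).
#' @return An object of class \code{"cr_model"}.
#' @export
assemble_model <- function(config, data) {
  stopifnot(inherits(config, "model_config"))
  data <- count_data(data)
  if (any(data$age > config$A))
    stop("data contain ages beyond A = ", config$A, call. = FALSE)
  areas <- sort(unique(data$area))
  genders <- sort(unique(data$gender))
  if (config$remission == "none" && any(data$measure == "rem"))
    stop("remission records present but the configuration excludes ",
         "remission; set remission = 'const' or 'spline'", call. = FALSE)
  if (config$hierarchical && length(areas) < 2)
    stop("hierarchical model requested with a single area", call. = FALSE)
  if (config$gender != "none" && length(genders) < 2)
    stop("gender = '", config$gender, "' requires data from two genders",
         call. = FALSE)
  if (config$gender == "none" && length(genders) > 1)
    stop("data contain multiple genders; choose gender = 'additive' or ",
         "'interaction' (or fit genders separately)", call. = FALSE)
  if (config$gender == "additive" &&
      !all(genders %in% c("female", "male")))
    stop("additive gender effects need gender levels 'female' and 'male'",
         call. = FALSE)

  priors <- config$priors
  if (config$hierarchical && is.null(priors$lambda_area))
    priors$lambda_area <- with(elicit_area_sd_prior(5, 50),
                               c(shape, rate))

  basis <- thinplate_basis(0:config$A, config$K)
  groups <- expand.grid(area = areas, gender = genders,
                        stringsAsFactors = FALSE)
  groups <- groups[order(groups$area, groups$gender), , drop = FALSE]
  rownames(groups) <- NULL

  # coefficient units: who gets an independent coefficient row
  units_of <- function() {
    if (config$gender == "interaction")
      group_key(groups$area, groups$gender)
    else areas
  }
  # Nonlinear spline coefficients and hierarchical intercepts are held
  # non-centred: the free parameters are standard-normal z-scores, and the
  # coefficient is lambda * z (intercept b1 + lambda1 * u).  This removes
  # the funnel degeneracy between a shrinkage scale and the coefficients it
  # shrinks, so the joint posterior mode is interior and samplers mix even
  # when the data leave the nonlinear terms weakly identified.
  K <- config$K
  skel <- list()
  skel$inc <- list(beta = matrix(0, length(units_of()), 2,
                                 dimnames = list(units_of(), NULL)),
                   z = matrix(0, length(units_of()), K - 2,
                              dimnames = list(units_of(), NULL)))
  if (!"lambda_inc" %in% names(config$fixed))
    skel$inc$loglambda <- 0
  if (config$gender == "additive") skel$inc$male <- numeric(K)

  if (config$hierarchical) {
    skel$cf <- list(u = stats::setNames(numeric(length(areas)), areas),
                    z = matrix(0, length(areas), K - 2,
                               dimnames = list(areas, NULL)),
                    b1 = 0, b2 = 0)
    if (!"lambda_area" %in% names(config$fixed)) skel$cf$loglambda1 <- 0
  } else {
    skel$cf <- list(beta = matrix(0, length(units_of()), 2,
                                  dimnames = list(units_of(), NULL)),
                    z = matrix(0, length(units_of()), K - 2,
                               dimnames = list(units_of(), NULL)))
  }
  if (!"lambda_cf" %in% names(config$fixed)) skel$cf$loglambda <- 0
  if (config$gender == "additive") skel$cf$male <- numeric(K)

  if (config$remission == "const") {
    skel$rem <- list(logr = 0)
  } else if (config$remission == "spline") {
    skel$rem <- list(beta = matrix(0, 1, 2), z = matrix(0, 1, K - 2))
    if (!"lambda_rem" %in% names(config$fixed)) skel$rem$loglambda <- 0
  }

  model <- structure(
    list(config = config, priors = priors, data = data, basis = basis,
         groups = groups, areas = areas, genders = genders,
         skeleton = skel, n_par = length(unlist(skel)),
         par_names = names(unlist(skel))),
    class = "cr_model")
  # precomputed observation indices for fast likelihood evaluation
  key <- group_key(data$area, data$gender)
  gkeys <- group_key(groups$area, groups$gender)
  model$obs <- list(
    rows = lapply(gkeys, function(k) which(key == k)),
    age1 = data$age + 1L,
    col = match(measure_col[data$measure], unname(measure_col)),
    num = data$num, denom = data$denom)
  model
}

#' @export
print.cr_model <- function(x, ...) {
  cfg <- x$config
  cat("Illness-death rate model\n")
  cat("  ages 0..", cfg$A, ", K = ", cfg$K, " basis terms\n", sep = "")
  cat("  areas: ", length(x$areas), "; genders: ",
      paste(x$genders, collapse = ", "), "\n", sep = "")
  cat("  remission: ", cfg$remission,
      "; hierarchical: ", cfg$hierarchical,
      "; gender: ", cfg$gender,
      "; trends: ", !is.null(cfg$trend_i) || !is.null(cfg$trend_f),
      "\n", sep = "")
  cat("  ", x$n_par, " free parameters; ", nrow(x$data), " data records\n",
      sep = "")
  invisible(x)
}

unflatten <- function(model, theta) {
  utils::relist(theta, model$skeleton)
}

# smoothness SD of one rate block: estimated (log scale) or fixed by config
rate_lambda <- function(model, pars, rate) {
  if (!is.null(pars[[rate]]$loglambda)) exp(pars[[rate]]$loglambda)
  else model$config$fixed[[paste0("lambda_", rate)]]
}

# full K-vector of spline coefficients for one rate and one group row,
# reassembled from the non-centred blocks
beta_for_group <- function(model, pars, rate, g) {
  cfg <- model$config
  area <- model$groups$area[g]
  gender <- model$groups$gender[g]
  unit <- if (cfg$gender == "interaction") group_key(area, gender) else area
  lam <- rate_lambda(model, pars, rate)
  if (rate == "cf" && cfg$hierarchical) {
    lam1 <- if (!is.null(pars$cf$loglambda1)) exp(pars$cf$loglambda1)
            else cfg$fixed$lambda_area
    beta <- c(pars$cf$b1 + lam1 * pars$cf$u[[unit]], pars$cf$b2,
              lam * pars$cf$z[unit, ])
  } else {
    beta <- c(pars[[rate]]$beta[unit, ], lam * pars[[rate]]$z[unit, ])
  }
  if (cfg$gender == "additive" && gender == "male" &&
      !is.null(pars[[rate]]$male))
    beta <- beta + pars[[rate]]$male
  beta
}

#' Transition rates implied by a parameter set
#'
#' @param model A \code{\link{assemble_model}} object.
#' @param pars Structured parameter list (as from \code{unflatten}) or a
#'   flat named vector on the unconstrained scale.
#' @return Named list (one element per group, keyed "area:gender") of
#'   \code{\link{rate_schedule}} objects.
#' @export
model_rates <- function(model, pars) {
  if (is.numeric(pars)) pars <- unflatten(model, pars)
  cfg <- model$config
  out <- vector("list", nrow(model$groups))
  names(out) <- group_key(model$groups$area, model$groups$gender)
  A <- cfg$A
  for (g in seq_len(nrow(model$groups))) {
    i <- rate_curve(beta_for_group(model, pars, "inc", g), model$basis,
                    cfg$inc$a_base, cfg$inc$increasing)
    f <- rate_curve(beta_for_group(model, pars, "cf", g), model$basis,
                    cfg$cf$a_base, cfg$cf$increasing)
    r <- switch(cfg$remission,
                none = rep(0, A + 1),
                const = rep(exp(pars$rem$logr), A + 1),
                spline = rate_curve(
                  c(pars$rem$beta[1, ],
                    rate_lambda(model, pars, "rem") * pars$rem$z[1, ]),
                  model$basis, cfg$rem$a_base, cfg$rem$increasing))
    out[[g]] <- rate_schedule(i, f, r)
  }
  out
}

#' Outcome probabilities implied by a parameter set
#'
#' Applies the deterministic multistate map (with the cohort time-trend
#' pathway if the configuration carries trend matrices) to each group's
#' rates.
#'
#' @inheritParams model_rates
#' @param S0 State occupancy at age 0.
#' @return Named list of per-age outcome probability data frames.
#' @export
model_outcome_probs <- function(model, pars, S0 = c(1, 0, 0)) {
  rates <- model_rates(model, pars)
  cfg <- model$config
  trended <- !is.null(cfg$trend_i) || !is.null(cfg$trend_f)
  lapply(rates, function(rs) {
    if (trended)
      suppressMessages(
        cohort_outcome_probabilities(rs, cfg$trend_i, cfg$trend_f, S0))
    else suppressMessages(outcome_probabilities(rs, S0))
  })
}

measure_col <- c(inc = "inc_prob", prev = "prev", mort = "mort_prob",
                 rem = "rem_prob")

#' Binomial log-likelihood of count data given rates
#'
#' Pointwise binomial log-probabilities of each record under the outcome
#' probabilities implied by the given rates.  Records with denominator 0
#' contribute exactly 0.  A record whose fitted probability is exactly 0
#' with a positive count (or 1 with count < denominator) contributes
#' \code{-Inf} and is flagged, never an error.
#'
#' @param data A \code{\link{count_data}} data frame.
#' @param rates A single \code{\link{rate_schedule}} (one homogeneous group)
#'   or a named list keyed \code{"area:gender"}.
#' @param S0 State occupancy at age 0.
#' @return List with \code{total}, \code{pointwise} (one value per record)
#'   and \code{flagged} (row indices with infinite contributions).
#' @export
log_likelihood <- function(data, rates, S0 = c(1, 0, 0)) {
  data <- count_data(data)
  if (inherits(rates, "rate_schedule")) {
    keys <- unique(group_key(data$area, data$gender))
    rates <- stats::setNames(rep(list(rates), length(keys)), keys)
  }
  probs <- lapply(rates, function(rs)
    suppressMessages(outcome_probabilities(rs, S0)))
  pw <- pointwise_loglik(data, probs)
  flagged <- which(!is.finite(pw))
  if (length(flagged))
    message("infinite log-likelihood contribution at record(s) ",
            paste(utils::head(flagged, 10), collapse = ","))
  list(total = sum(pw), pointwise = pw, flagged = flagged)
}

pointwise_loglik <- function(data, probs, clamp = FALSE) {
  key <- group_key(data$area, data$gender)
  p <- numeric(nrow(data))
  for (k in unique(key)) {
    rows <- key == k
    tab <- probs[[k]]
    if (is.null(tab))
      stop("no outcome probabilities for group ", k, call. = FALSE)
    col <- measure_col[data$measure[rows]]
    p[rows] <- tab[cbind(data$age[rows] + 1L,
                         match(col, names(tab)))]
  }
  if (clamp) p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  ll <- stats::dbinom(data$num, data$denom, p, log = TRUE)
  ll[data$denom == 0L] <- 0
  ll
}

model_loglik_pointwise <- function(model, pars) {
  if (is.numeric(pars)) pars <- unflatten(model, pars)
  cfg <- model$config
  if (!is.null(cfg$trend_i) || !is.null(cfg$trend_f))
    return(pointwise_loglik(model$data, model_outcome_probs(model, pars)))
  obs <- model$obs
  p <- numeric(length(obs$age1))
  A1 <- cfg$A + 1L
  for (g in seq_len(nrow(model$groups))) {
    rows <- obs$rows[[g]]
    if (!length(rows)) next
    i <- rate_curve(beta_for_group(model, pars, "inc", g), model$basis,
                    cfg$inc$a_base, cfg$inc$increasing)
    f <- rate_curve(beta_for_group(model, pars, "cf", g), model$basis,
                    cfg$cf$a_base, cfg$cf$increasing)
    r <- switch(cfg$remission,
                none = numeric(A1),
                const = rep(exp(pars$rem$logr), A1),
                spline = rate_curve(
                  c(pars$rem$beta[1, ],
                    rate_lambda(model, pars, "rem") * pars$rem$z[1, ]),
                  model$basis, cfg$rem$a_base, cfg$rem$increasing))
    M <- outcome_prob_mat(i, f, r)
    p[rows] <- M[cbind(obs$age1[rows], obs$col[rows])]
  }
  # saturated probabilities (numerical 0/1 under extreme parameter values)
  # are clamped so optimisers and importance weights stay finite
  p <- pmin(pmax(p, 1e-300), 1 - 1e-15)
  ll <- stats::dbinom(obs$num, obs$denom, p, log = TRUE)
  ll[obs$denom == 0L] <- 0
  ll
}

model_log_prior <- function(model, pars) {
  if (is.numeric(pars)) pars <- unflatten(model, pars)
  pr <- model$priors
  cfg <- model$config
  lp <- 0
  dn <- function(x, ms) sum(stats::dnorm(x, ms[1], ms[2], log = TRUE))
  # gamma prior on an SD sampled as log(SD): add the Jacobian log(SD)
  dlam <- function(loglam, sr) {
    stats::dgamma(exp(loglam), shape = sr[1], rate = sr[2], log = TRUE) +
      loglam
  }
  # non-centred spline block: free intercept/slope, standard-normal
  # z-scores, gamma-prior smoothness SD
  spline_block <- function(block) {
    dn(block$beta[, 1], pr$intercept) + dn(block$beta[, 2], pr$slope) +
      dn(block$z, c(0, 1)) +
      (if (!is.null(block$loglambda)) dlam(block$loglambda, pr$lambda)
       else 0)
  }
  lp <- lp + spline_block(pars$inc)
  if (cfg$hierarchical) {
    lp <- lp + dn(pars$cf$u, c(0, 1)) + dn(pars$cf$z, c(0, 1)) +
      dn(pars$cf$b1, pr$b1) + dn(pars$cf$b2, pr$b2)
    if (!is.null(pars$cf$loglambda1))
      lp <- lp + dlam(pars$cf$loglambda1, pr$lambda_area)
    if (!is.null(pars$cf$loglambda))
      lp <- lp + dlam(pars$cf$loglambda, pr$lambda)
  } else {
    lp <- lp + spline_block(pars$cf)
  }
  # gender offsets
  for (blk in c("inc", "cf")) {
    m <- pars[[blk]]$male
    if (!is.null(m)) {
      lmale <- if (length(pr$lambda_male) == 1) pr$lambda_male
               else stop("estimated lambda_male not supported; fix a value",
                         call. = FALSE)
      lp <- lp + dn(m[1:2], c(0, pr$gender_sd)) +
        (if (length(m) > 2) dn(m[-(1:2)], c(0, lmale)) else 0)
    }
  }
  # remission
  if (cfg$remission == "const")
    lp <- lp + dn(pars$rem$logr, pr$intercept)
  if (cfg$remission == "spline")
    lp <- lp + spline_block(pars$rem)
  lp
}

#' Unnormalised log posterior density on the unconstrained scale
#'
#' @param model A \code{"cr_model"}.
#' @param theta Flat parameter vector of length \code{model$n_par}.
#' @return A single number; \code{-Inf} where the likelihood degenerates.
#' @export
model_log_post <- function(model, theta) {
  pars <- unflatten(model, theta)
  lp <- model_log_prior(model, pars)
  if (!is.finite(lp)) return(-Inf)
  ll <- sum(model_loglik_pointwise(model, pars))
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

# crude data-driven starting values: intercepts at log crude rates,
# slopes and nonlinear terms 0, hyperparameters at prior means
model_init <- function(model) {
  pars <- model$skeleton
  d <- model$data
  crude <- function(meas, default) {
    n <- sum(d$denom[d$measure == meas])
    if (n == 0) return(default)
    max(sum(d$num[d$measure == meas]) / n, 1e-5)
  }
  p_inc <- crude("inc", 1e-3)
  p_prev <- crude("prev", 1e-2)
  p_mort <- crude("mort", 1e-3)
  i0 <- -log(1 - min(p_inc, 0.99))
  f0 <- min(max(p_mort / max(p_prev, 1e-4), 1e-4), 5)
  inc_int <- log(i0)
  cf_int <- log(f0)
  # under the increasing (log-increment) parameterisation the intercept sets
  # the per-age increment; aim the cumulative curve at the crude level
  n_inc_ages <- max(model$config$A - model$config$inc$a_base, 1)
  if (model$config$inc$increasing) inc_int <- inc_int - log(n_inc_ages / 2)
  n_cf_ages <- max(model$config$A - model$config$cf$a_base, 1)
  if (model$config$cf$increasing) cf_int <- cf_int - log(n_cf_ages / 2)
  pars$inc$beta[, 1] <- inc_int
  if (model$config$hierarchical) {
    pars$cf$b1 <- cf_int
    pars$cf$b2 <- model$priors$b2[1]
    if (!is.null(pars$cf$loglambda1))
      pars$cf$loglambda1 <-
        log(model$priors$lambda_area[1] / model$priors$lambda_area[2])
  } else {
    pars$cf$beta[, 1] <- cf_int
  }
  lam_mean <- model$priors$lambda[1] / model$priors$lambda[2]
  for (blk in c("inc", "cf", "rem"))
    if (!is.null(pars[[blk]]$loglambda))
      pars[[blk]]$loglambda <- log(lam_mean)
  if (model$config$remission == "const")
    pars$rem$logr <- log(max(crude("rem", 0.05), 1e-4))
  if (model$config$remission == "spline")
    pars$rem$beta[, 1] <- log(max(crude("rem", 0.05), 1e-4))
  stats::setNames(unlist(pars), model$par_names)
}
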