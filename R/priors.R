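#' Prior settings for the Bayesian model
#'
#' Defaults follow the package's reference analysis: vague Normal(0, 100^2)
#' priors for single-population spline intercepts and slopes; Gamma(2, 1)
#' for each smoothness standard deviation lambda0 (a prior that vanishes at
#' zero, which keeps the posterior mode away from the boundary); for the
#' hierarchical model, Normal(0, 10^2) for the mean intercept b1 and
#' Normal(5, 5^2) for the common slope b2 (slopes act on age scaled to
#' [0, 1], so b2 = 5 means roughly a 150-fold rate increase across the age
#' span); Normal(0, 0.82^2) for the gender effect on intercept and slope,
#' implying a 95% prior interval of about 0.2 to 5 for the male/female rate
#' ratio; and a gamma prior for the between-area SD lambda1 elicited from
#' fold-ratio judgements (default: 5-fold guess, 50-fold upper limit, see
#' \code{\link{elicit_area_sd_prior}}).
#'
#' @param intercept,slope Length-2 (mean, sd) normal priors for
#'   non-hierarchical spline intercepts and slopes.
#' @param lambda Length-2 (shape, rate) gamma prior for each smoothness SD.
#' @param b1,b2 Length-2 (mean, sd) normal priors for the hierarchical mean
#'   intercept and common slope.
#' @param gender_sd SD of the normal prior for gender effects on intercept
#'   and slope.
#' @param lambda_area Length-2 (shape, rate) gamma prior for the
#'   between-area SD, or \code{NULL} to elicit the default at model assembly.
#' @param lambda_male Fixed value of the SD of gender effects on nonlinear
#'   coefficients, or a length-2 (shape, rate) gamma prior to estimate it.
#' @return A list of class \code{"prior_set"}.
#' @export
prior_set <- function(intercept = c(0, 100), slope = c(0, 100),
                      lambda = c(2, 1), b1 = c(0, 10), b2 = c(5, 5),
                      gender_sd = 0.82, lambda_area = NULL,
                      lambda_male = 1) {
  for (nm in c("intercept", "slope", "b1", "b2")) {
    v <- get(nm)
    if (length(v) != 2 || v[2] <= 0)
      stop("prior '", nm, "' must be (mean, sd) with sd > 0", call. = FALSE)
  }
  if (any(lambda <= 0)) stop("lambda prior must have positive shape and rate",
                             call. = FALSE)
  if (gender_sd <= 0) stop("gender_sd must be positive", call. = FALSE)
  structure(list(intercept = intercept, slope = slope, lambda = lambda,
                 b1 = b1, b2 = b2, gender_sd = gender_sd,
                 lambda_area = lambda_area, lambda_male = lambda_male),
            class = "prior_set")
}

# standard normal 97.5% point, used wherever a 95% interval is converted to
# and from an SD
Z975 <- 1.959964

#' Elicit a gamma prior for the between-area standard deviation
#'
#' The between-area variation in log case fatality is summarised for
#' elicitation as the fold-ratio in case fatality between a "high-risk" and
#' "low-risk" area, defined as the 97.5\% and 2.5\% quantiles of the area
#' distribution: a between-area SD of lambda1 implies a ratio of
#' exp(2 * 1.959964 * lambda1).  Given a prior guess at this ratio and a
#' plausible upper limit, a numerical search finds the gamma(shape, rate)
#' prior for lambda1 whose mean reproduces the guess and whose 97.5\%
#' quantile reproduces the upper limit.
#'
#' @param ratio_guess Prior guess at the high/low fold-ratio (> 1).
#' @param ratio_upper Plausible upper limit for the ratio
#'   (> \code{ratio_guess}).
#' @param tol Relative tolerance of the round-trip check.
#' @return List with \code{shape}, \code{rate}, the implied \code{mean} and
#'   97.5\% quantile \code{q975} of lambda1, and the round-tripped
#'   \code{ratio_at_mean} and \code{ratio_at_q975}.
#' @examples
#' p <- elicit_area_sd_prior(5, 50)
#' exp(2 * 1.959964 * p$mean)   # recovers 5
#' @export
elicit_area_sd_prior <- function(ratio_guess, ratio_upper, tol = 1e-6) {
  if (!is.finite(ratio_guess) || !is.finite(ratio_upper) ||
      ratio_guess <= 1 || ratio_upper <= ratio_guess)
    stop("need 1 < ratio_guess < ratio_upper", call. = FALSE)
  m_target <- log(ratio_guess) / (2 * Z975)
  q_target <- log(ratio_upper) / (2 * Z975)
  # with rate = shape / m_target, the 97.5% quantile divided by the mean is
  # a strictly decreasing function of shape: search on log(shape)
  qratio <- function(logshape) {
    shape <- exp(logshape)
    stats::qgamma(0.975, shape = shape, rate = shape / m_target) / m_target
  }
  target <- q_target / m_target
  # qratio is strictly decreasing in shape (to 1 as shape -> Inf); scan for
  # a bracket, avoiding the tiny-shape region where qgamma underflows
  grid <- seq(12, -12, by = -0.5)
  vals <- vapply(grid, qratio, 0)
  usable <- is.finite(vals) & vals > 0
  below <- which(usable & vals < target)
  above <- which(usable & vals >= target)
  if (!length(below) || !length(above))
    stop("elicitation search failed: requested quantile/mean ratio ",
         signif(target, 4), " is not attainable by a gamma prior",
         call. = FALSE)
  lo <- grid[min(above)]          # smaller logshape, ratio above target
  hi <- grid[max(below)]          # larger logshape, ratio below target
  root <- stats::uniroot(function(ls) qratio(ls) - target, c(lo, hi),
                         tol = 1e-12)
  shape <- exp(root$root)
  rate <- shape / m_target
  mean <- shape / rate
  q975 <- stats::qgamma(0.975, shape = shape, rate = rate)
  out <- list(shape = shape, rate = rate, mean = mean, q975 = q975,
              ratio_at_mean = exp(2 * Z975 * mean),
              ratio_at_q975 = exp(2 * Z975 * q975))
  if (abs(out$ratio_at_mean / ratio_guess - 1) > tol ||
      abs(out$ratio_at_q975 / ratio_upper - 1) > tol)
    stop("elicitation search did not converge: implied ratios (",
         signif(out$ratio_at_mean, 6), ", ", signif(out$ratio_at_q975, 6),
         ") vs requested (", ratio_guess, ", ", ratio_upper, ")",
         call. = FALSE)
  out
}

#' Quantiles of the prior rate ratio implied by the gender-effect prior
#'
#' The additive gender effect on the log rate has a Normal(0, sd^2) prior,
#' so the implied male/female rate ratio is log-normal; this returns its
#' central 95\% interval.
#'
#' @param sd Prior SD of the gender effect on the log scale (default the
#'   package's 0.82).
#' @return Length-2 vector: 2.5\% and 97.5\% quantiles of the rate ratio.
#' @export
gender_ratio_interval <- function(sd = 0.82) {
  stats::qlnorm(c(0.025, 0.975), meanlog = 0, sdlog = sd)
}
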