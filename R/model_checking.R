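#' Conflict p-value between a direct observation and an indirect synthesis
#'
#' Compares the information a single count provides about its underlying
#' probability with the posterior implied by the rest of the model.  The
#' direct evidence is summarised by the conjugate posterior
#' Beta(y + 0.5, n - y + 0.5) (binomial likelihood with a Jeffreys
#' Beta(0.5, 0.5) prior); the indirect evidence by posterior draws of the
#' corresponding fitted probability.  The tail probability
#' q = Pr(p < p_full) is computed by averaging the Beta posterior CDF over
#' the draws of p_full (Rao-Blackwellised, which removes draw-vs-draw Monte
#' Carlo noise), and the two-sided conflict p-value is 2 min(q, 1 - q).
#'
#' @param y,n Observed numerator and denominator (n = 0 reduces to the
#'   Beta(0.5, 0.5) prior alone).
#' @param p_full_draws Posterior draws of the fitted probability.
#' @return List with \code{q} and \code{p_value} (in (0, 1]).
#' @examples
#' conflict_pvalue(5, 10, rep(0.5, 100))$p_value   # exactly 1 by symmetry
#' @export
conflict_pvalue <- function(y, n, p_full_draws) {
  if (length(p_full_draws) == 0)
    stop("p_full_draws is empty", call. = FALSE)
  if (any(p_full_draws < 0 | p_full_draws > 1))
    stop("p_full_draws must lie in [0, 1]", call. = FALSE)
  if (y < 0 || n < 0 || y > n)
    stop("need 0 <= y <= n", call. = FALSE)
  q <- mean(stats::pbeta(p_full_draws, y + 0.5, n - y + 0.5))
  p <- 2 * min(q, 1 - q)
  list(q = q, p_value = max(p, .Machine$double.xmin))
}

#' Leave-one-out expected log predictive density
#'
#' Estimates the pointwise expected log predictive density elpd_i of each
#' observation under leave-one-out cross-validation, from the posterior
#' pointwise log-likelihood matrix, using Pareto-smoothed importance
#' sampling: the raw importance ratios 1/p(y_i | theta_s) have their upper
#' tail replaced by expected order statistics of a generalised Pareto
#' distribution fitted to that tail, then truncated at the raw maximum.
#' The tail shape estimate k is returned per observation as a reliability
#' diagnostic (k > 0.7 indicates an unreliable estimate).
#'
#' Degenerate columns (all draws identical, so importance weights carry no
#' information) fall back to the plain log pointwise predictive density and
#' are flagged.
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws x observations
#'   (as stored in a \code{"cr_fit"} under \code{$loglik}).
#' @return Object of class \code{"cr_loo"}: list with \code{pointwise}
#'   (data frame: elpd, pareto_k, degenerate), \code{elpd} (the total),
#'   and \code{n_draws}.
#' @export
loo_elpd <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (any(!is.finite(loglik)))
    stop("log-likelihood matrix must be finite", call. = FALSE)
  S <- nrow(loglik)
  N <- ncol(loglik)
  elpd <- numeric(N)
  k <- rep(NA_real_, N)
  degen <- logical(N)
  for (j in seq_len(N)) {
    ll <- loglik[, j]
    if (S == 1 || stats::sd(ll) < 1e-12) {
      elpd[j] <- mean(ll)
      degen[j] <- S > 1
      next
    }
    lw <- -ll                      # log importance ratios for LOO
    sm <- psis_smooth(lw)
    k[j] <- sm$k
    lw <- sm$lw
    # elpd_i = log( sum w_s p(y_i|theta_s) / sum w_s )
    elpd[j] <- logsumexp(lw + ll) - logsumexp(lw)
  }
  if (any(degen))
    message("plain log predictive density used for ", sum(degen),
            " observation(s) with degenerate importance weights")
  structure(list(pointwise = data.frame(elpd = elpd, pareto_k = k,
                                        degenerate = degen),
                 elpd = sum(elpd), n_draws = S),
            class = "cr_loo")
}

#' @export
print.cr_loo <- function(x, ...) {
  cat("LOO expected log predictive density\n")
  cat("  total elpd: ", round(x$elpd, 2), " over ",
      nrow(x$pointwise), " observations (", x$n_draws, " draws)\n", sep = "")
  kk <- x$pointwise$pareto_k
  if (any(is.finite(kk) & kk > 0.7))
    cat("  ", sum(kk > 0.7, na.rm = TRUE),
        " observation(s) with Pareto k > 0.7: estimates unreliable\n",
        sep = "")
  invisible(x)
}

#' Compare two fitted models by LOO
#'
#' @param loo1,loo2 Results of \code{\link{loo_elpd}} on the same data.
#' @return List with the elpd difference (model 1 minus model 2) and its
#'   standard error from the pointwise differences.
#' @export
loo_compare_elpd <- function(loo1, loo2) {
  d <- loo1$pointwise$elpd - loo2$pointwise$elpd
  if (length(loo1$pointwise$elpd) != length(loo2$pointwise$elpd))
    stop("fits cover different numbers of observations", call. = FALSE)
  list(elpd_diff = sum(d), se_diff = stats::sd(d) * sqrt(length(d)))
}

# Pareto-smooth a vector of log importance weights (normalised internally).
# Tail size, fitting and truncation follow the standard smoothed importance
# sampling recipe; the GPD fit is the Zhang-Stephens profile posterior-mean
# estimator.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || S < 25)
    return(list(lw = pmin(lw, 0), k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exc <= 0)) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exc)
  k <- fit$k
  if (is.finite(k)) {
    # replace tail by expected order statistics of the fitted GPD
    p <- (seq_len(M) - 0.5) / M
    qs <- gpd_quantile(p, k, fit$sigma)
    smoothed <- log(qs + exp(cutoff))
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  lw <- pmin(lw, 0)   # truncate at the raw maximum (weights were max-scaled)
  list(lw = lw, k = k)
}

# Zhang & Stephens (2009) estimator of the generalised Pareto shape k and
# scale sigma, parameterised so the density is
# (1/sigma) (1 + k z / sigma)^(-1/k - 1)
gpd_fit <- function(z) {
  n <- length(z)
  z <- sort(z)
  prior_b <- 3
  m <- 30 + floor(sqrt(n))
  b <- 1 / z[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_b * stats::quantile(z, 0.25, names = FALSE))
  lik <- function(bb) {
    kk <- -mean(log1p(-bb * z))
    n * (log(bb / kk) + kk - 1)
  }
  lb <- vapply(b, lik, 0)
  w <- exp(lb - logsumexp(lb))
  b_hat <- sum(b * w)
  k <- -mean(log1p(-b_hat * z))
  sigma <- k / b_hat
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fitted-versus-observed comparison table
#'
#' Compares each observed proportion with the posterior of the theoretical
#' probability assumed to generate it, and attaches a conflict p-value per
#' record.  Records with denominator 0 are excluded (with a note); cells of
#' the fit not covered by data are listed in the \code{"missing"} attribute
#' rather than causing an error.
#'
#' @param fit A \code{"cr_fit"} on a full model (draws of outcome
#'   probabilities present).
#' @param data A \code{\link{count_data}} data frame; defaults to the data
#'   the model was fitted to.
#' @return Data frame with one row per record: observed proportion, fitted
#'   posterior median and 95\% interval (plus \code{fitted_mode} for the
#'   Laplace engine), and the conflict p-value.
#' @export
fitted_vs_observed <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "cr_fit"), !is.null(fit$gen))
  model <- fit$model
  if (is.null(data)) data <- model$data
  data <- count_data(data)
  drop0 <- data$denom == 0L
  if (any(drop0))
    message(sum(drop0), " record(s) with denominator 0 excluded")
  data <- data[!drop0, , drop = FALSE]
  key <- group_key(data$area, data$gender)
  missing_groups <- setdiff(unique(key), names(fit$gen))
  if (length(missing_groups)) {
    data <- data[!key %in% missing_groups, , drop = FALSE]
    key <- group_key(data$area, data$gender)
  }
  mode_probs <- NULL
  if (fit$engine == "laplace")
    mode_probs <- model_outcome_probs(model, unflatten(model, fit$mode))
  n <- nrow(data)
  med <- lo <- hi <- mo <- pv <- numeric(n)
  for (row in seq_len(n)) {
    q <- measure_col[[data$measure[row]]]
    dcol <- fit$gen[[key[row]]][[q]][, data$age[row] + 1L]
    med[row] <- stats::median(dcol)
    lo[row] <- stats::quantile(dcol, 0.025, names = FALSE)
    hi[row] <- stats::quantile(dcol, 0.975, names = FALSE)
    if (!is.null(mode_probs))
      mo[row] <- mode_probs[[key[row]]][data$age[row] + 1L, q]
    pv[row] <- conflict_pvalue(data$num[row], data$denom[row],
                               clamp01(dcol))$p_value
  }
  out <- data.frame(
    area = data$area, gender = data$gender, age = data$age,
    measure = data$measure, num = data$num, denom = data$denom,
    observed = data$num / data$denom,
    fitted_median = med, fitted_lower = lo, fitted_upper = hi)
  if (!is.null(mode_probs)) out$fitted_mode <- mo
  out$conflict_p <- pv
  attr(out, "missing") <- missing_groups
  out
}
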