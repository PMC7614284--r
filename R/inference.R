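# Both engines work on any object exposing a log posterior over a flat
# unconstrained parameter vector: a "cr_model", or a plain list with
# elements n_par, par_names (optional) and log_post(theta) — the latter is
# handy for testing the engines on analytically tractable densities.

obj_log_post <- function(model, theta) {
  if (is.function(model$log_post)) model$log_post(theta)
  else model_log_post(model, theta)
}

obj_init <- function(model) {
  if (!is.null(model$init)) {
    if (is.function(model$init)) model$init() else model$init
  } else model_init(model)
}

obj_par_names <- function(model) {
  if (!is.null(model$par_names)) model$par_names
  else paste0("par", seq_len(model$n_par))
}

#' Posterior mode with multivariate normal (Laplace) approximation
#'
#' Finds the mode of the posterior on the unconstrained parameter space by
#' quasi-Newton (BFGS) optimisation, forms the second-order (normal)
#' approximation to the posterior from the curvature at the mode, and draws
#' a sample from that normal which is mapped back to rates and outcome
#' probabilities.  This is the fast engine: orders of magnitude cheaper than
#' sampling, with intervals that agree closely with MCMC quantiles when the
#' posterior is roughly quadratic on the unconstrained scale.
#'
#' By default (\code{fix_smoothness = TRUE}, full models only) the fit is
#' two-stage: the joint posterior including the smoothness standard
#' deviations is optimised first; the smoothness SDs (and the between-area
#' SD, if estimated) are then held fixed at their modal values while the
#' normal approximation is formed over the remaining parameters.  Because
#' the spline coefficients are held non-centred (coefficient = SD x
#' z-score), fixing the SDs makes the map from parameters to log-rate
#' curves linear, so the normal approximation translates to well-calibrated
#' intervals on the rates; with the SDs free, normal draws of the SD and
#' z-score multiply into an overdispersed curve distribution.  The returned
#' fit's \code{model} element is the reduced model with those SDs fixed.
#'
#' If the optimiser fails to converge, up to 4 restarts from jittered
#' starting values are attempted before failing with the values tried.  A
#' non-positive-definite Hessian is repaired by adding the smallest diagonal
#' jitter in 1e-8..1e-2 that achieves positive definiteness (recorded in the
#' result).
#'
#' @param model A model from \code{\link{assemble_model}} (or any object
#'   with \code{n_par} and a \code{log_post} function).
#' @param seed Integer seed governing the normal draws (and restart jitter).
#' @param n_draws Number of draws from the normal approximation.
#' @param init Optional starting vector (default: crude data-driven values).
#' @param maxit Maximum BFGS iterations.
#' @param fix_smoothness Fix estimated scale hyperparameters at their joint
#'   modal values before forming the normal approximation (see Details).
#' @return An object of class \code{"cr_fit"} with elements \code{mode}
#'   (named vector), \code{vcov}, \code{draws} (n_draws x n_par),
#'   \code{logpost}, \code{gen} (per-group draws of rates and outcome
#'   probabilities, for a \code{cr_model}), \code{loglik} (draws x records)
#'   and \code{diagnostics} (including \code{full_mode}, the stage-one mode
#'   over all parameters).
#' @export
fit_mode_laplace <- function(model, seed = 1, n_draws = 1000, init = NULL,
                             maxit = 2000, fix_smoothness = TRUE) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  full_mode <- NULL
  if (fix_smoothness && inherits(model, "cr_model") &&
      any(grepl("loglambda", model$par_names))) {
    stage1 <- fit_mode_laplace(model, seed = seed, n_draws = 0,
                               init = init, maxit = maxit,
                               fix_smoothness = FALSE)
    full_mode <- stage1$mode
    fixed <- model$config$fixed
    map <- c(inc.loglambda = "lambda_inc", cf.loglambda = "lambda_cf",
             rem.loglambda = "lambda_rem", cf.loglambda1 = "lambda_area")
    for (nm in names(map))
      if (nm %in% names(full_mode)) fixed[[map[[nm]]]] <- exp(full_mode[[nm]])
    config2 <- model$config
    config2$fixed <- fixed
    model <- assemble_model(config2, model$data)
    init <- full_mode[model$par_names]
  }
  nlp <- function(theta) {
    v <- obj_log_post(model, theta)
    if (!is.finite(v)) 1e10 else -v
  }
  # analytic reverse-mode gradient where available (full models without
  # calendar-time trends); otherwise optim falls back to finite differences
  ngr <- NULL
  if (inherits(model, "cr_model") &&
      is.null(model$config$trend_i) && is.null(model$config$trend_f))
    ngr <- function(theta) {
      gv <- -model_log_post_grad(model, theta)
      gv[!is.finite(gv)] <- 0
      gv
    }
  theta0 <- if (is.null(init)) obj_init(model) else init
  # a named init from a differently configured fit (e.g. one with scale
  # hyperparameters estimated rather than fixed) is aligned by name
  if (!is.null(names(theta0)) && inherits(model, "cr_model") &&
      !identical(names(theta0), model$par_names)) {
    base0 <- obj_init(model)
    common <- intersect(names(theta0), names(base0))
    base0[common] <- theta0[common]
    theta0 <- base0
  }
  tried <- list()
  opt <- NULL
  for (attempt in 0:4) {
    start <- if (attempt == 0) theta0
             else theta0 + stats::rnorm(length(theta0), 0, 0.3 * attempt)
    tried[[attempt + 1]] <- start
    o <- stats::optim(start, nlp, gr = ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-9))
    if (o$convergence == 0 && is.finite(o$value) && o$value < 1e9) {
      # polish: restart the quasi-Newton approximation at the candidate
      # mode (helps in high dimension, where BFGS can stall)
      o2 <- stats::optim(o$par, nlp, gr = ngr, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-9))
      if (o2$value <= o$value) o <- o2
      opt <- o; break
    }
  }
  if (is.null(opt))
    stop("mode-finding failed to converge after 5 starts; starting values ",
         "tried:\n", paste(vapply(tried, function(s)
           paste(signif(utils::head(s, 6), 3), collapse = ", "), ""),
           collapse = "\n"), call. = FALSE)
  mode <- stats::setNames(opt$par, obj_par_names(model))
  if (n_draws == 0)   # mode only (stage-one call): skip curvature and draws
    return(structure(list(engine = "laplace", model = model, mode = mode,
                          logpost = -opt$value,
                          diagnostics = list(convergence = opt$convergence,
                                             counts = opt$counts)),
                     class = "cr_fit"))
  H <- if (is.null(ngr)) stats::optimHess(opt$par, nlp)
       else stats::optimHess(opt$par, nlp, gr = ngr)
  H <- (H + t(H)) / 2
  jitter_used <- 0
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) {
    for (j in 10^seq(-8, -2, by = 1)) {
      R <- tryCatch(chol(H + diag(j, nrow(H))), error = function(e) NULL)
      if (!is.null(R)) { jitter_used <- j; break }
    }
  }
  if (is.null(R)) {
    # last resort: floor the curvature spectrum (finite-difference noise can
    # leave small negative eigenvalues in flat directions)
    e <- eigen(H, symmetric = TRUE)
    floor_at <- max(e$values) * 1e-8
    H <- e$vectors %*% (pmax(e$values, floor_at) * t(e$vectors))
    R <- chol((H + t(H)) / 2)
    jitter_used <- NA_real_
  }
  vcov <- chol2inv(R)
  dimnames(vcov) <- list(names(mode), names(mode))
  z <- matrix(stats::rnorm(n_draws * length(mode)), n_draws)
  draws <- sweep(z %*% chol(vcov), 2, mode, `+`)
  colnames(draws) <- names(mode)
  fit <- structure(
    list(engine = "laplace", model = model, mode = mode,
         logpost = -opt$value, vcov = vcov, draws = draws,
         diagnostics = list(convergence = opt$convergence,
                            counts = opt$counts,
                            hessian_jitter = jitter_used,
                            full_mode = full_mode)),
    class = "cr_fit")
  if (inherits(model, "cr_model")) fit <- add_generated(fit)
  fit
}

#' Sample the full posterior
#'
#' Full-posterior inference by Markov chain Monte Carlo on the unconstrained
#' parameter space.  Each update mixes two Metropolis-Hastings kernels built
#' from the Laplace approximation at the posterior mode: an independence
#' proposal from a heavy-tailed multivariate t centred at the mode (which
#' yields nearly uncorrelated draws wherever the posterior is close to its
#' normal approximation) and a random-walk proposal with covariance scaled
#' from the Laplace curvature, whose step size adapts during warmup towards
#' an acceptance rate of 0.234 (which guarantees exploration where the
#' normal approximation is poor).  Chains are run sequentially with seeds
#' derived from \code{seed}, so runs are exactly reproducible.
#'
#' Convergence is summarised by split-Rhat and effective sample size per
#' parameter; values of Rhat above 1.01 produce a warning, not an error.
#'
#' @inheritParams fit_mode_laplace
#' @param chains Number of chains.
#' @param iter Post-warmup iterations per chain.
#' @param warmup Warmup (adaptation) iterations per chain, discarded.
#' @param max_gen Cap on the number of retained draws used for generated
#'   quantities (rates, outcome probabilities, pointwise log-likelihood);
#'   retained draws are thinned evenly to this count.
#' @return A \code{"cr_fit"} with \code{draws} (all post-warmup draws,
#'   stacked), \code{chain}/\code{iteration} indices, \code{diagnostics}
#'   (data frame with rhat and ess per parameter), and generated quantities
#'   as in \code{\link{fit_mode_laplace}}.
#' @export
sample_posterior <- function(model, chains = 4, iter = 2000,
                             warmup = 1000, seed = 1, init = NULL,
                             max_gen = 2000) {
  seed <- as.integer(seed) %% .Machine$integer.max
  base <- fit_mode_laplace(model, seed = seed, n_draws = 2, init = init,
                           fix_smoothness = FALSE)
  mode <- base$mode
  Sigma <- base$vcov
  d <- length(mode)
  C <- chol((2.38^2 / d) * (Sigma + diag(1e-12, d)))
  lp_fun <- function(theta) obj_log_post(model, theta)
  # independence kernel: multivariate t_7 centred at the mode with inflated
  # Laplace scale (heavy tails dominate the posterior tails, keeping the
  # importance-style acceptance ratio well behaved)
  t_df <- 7
  Ct <- chol(1.3 * (Sigma + diag(1e-12, d)))
  Ct_inv <- backsolve(Ct, diag(d))
  t_logdet <- sum(log(diag(Ct)))
  t_logdens <- function(theta) {
    z <- drop(crossprod(Ct_inv, theta - mode))
    -(t_df + d) / 2 * log1p(sum(z^2) / t_df) - t_logdet
  }
  r_t <- function() {
    z <- stats::rnorm(d) / sqrt(stats::rchisq(1, t_df) / t_df)
    mode + drop(z %*% Ct)
  }

  all_draws <- vector("list", chains)
  all_lp <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 1000003L * ch) %% .Machine$integer.max)
    theta <- mode + drop(stats::rnorm(d) %*% C)
    lp <- lp_fun(theta)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      theta <- mode + drop(stats::rnorm(d) %*% C) * 0.1
      lp <- lp_fun(theta)
      tries <- tries + 1
    }
    if (!is.finite(lp))
      stop("chain ", ch, ": could not find a finite starting density near ",
           "the mode; last start: ",
           paste(signif(utils::head(theta, 6), 3), collapse = ", "),
           call. = FALSE)
    logscale <- 0
    keep <- matrix(NA_real_, iter, d)
    lps <- numeric(iter)
    nacc <- 0
    total <- warmup + iter
    qcur <- t_logdens(theta)
    for (it in seq_len(total)) {
      if (stats::runif(1) < 0.4) {
        # independence step
        prop <- r_t()
        lpp <- lp_fun(prop)
        qprop <- t_logdens(prop)
        ratio <- (lpp - qprop) - (lp - qcur)
        acc <- 0
        if (is.finite(lpp) && log(stats::runif(1)) < ratio) {
          theta <- prop; lp <- lpp; qcur <- qprop; acc <- 1
        }
      } else {
        # random-walk step with adaptive scale
        prop <- theta + exp(logscale) * drop(stats::rnorm(d) %*% C)
        lpp <- lp_fun(prop)
        acc <- 0
        if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
          theta <- prop; lp <- lpp; qcur <- t_logdens(theta); acc <- 1
        }
        if (it <= warmup)
          logscale <- logscale + (acc - 0.234) / sqrt(it)
      }
      if (it > warmup) {
        nacc <- nacc + acc
        keep[it - warmup, ] <- theta
        lps[it - warmup] <- lp
      }
    }
    all_draws[[ch]] <- keep
    all_lp[[ch]] <- lps
    accept[ch] <- nacc / iter
  }
  draws <- do.call(rbind, all_draws)
  colnames(draws) <- obj_par_names(model)
  diag_df <- data.frame(
    parameter = colnames(draws),
    rhat = vapply(seq_len(d), function(j)
      split_rhat(lapply(all_draws, function(m) m[, j])), 0),
    ess = vapply(seq_len(d), function(j)
      sum(vapply(all_draws, function(m)
        as.numeric(coda::effectiveSize(m[, j])), 0)), 0))
  bad <- diag_df$rhat > 1.01
  if (any(bad, na.rm = TRUE))
    warning(sum(bad, na.rm = TRUE), " parameter(s) with split-Rhat > 1.01 ",
            "(max ", round(max(diag_df$rhat, na.rm = TRUE), 3),
            "); consider more iterations", call. = FALSE)
  fit <- structure(
    list(engine = "sample", model = model, draws = draws,
         chain = rep(seq_len(chains), each = iter),
         iteration = rep(seq_len(iter), chains),
         logpost_draws = unlist(all_lp),
         accept_rate = accept, diagnostics = diag_df),
    class = "cr_fit")
  if (inherits(model, "cr_model")) fit <- add_generated(fit, max_gen)
  fit
}

# split-Rhat: split each chain in half, compare within- to between-half
# variance (rank-free classic form)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# map retained draws to rates, outcome probabilities and the pointwise
# log-likelihood matrix
add_generated <- function(fit, max_gen = Inf) {
  model <- fit$model
  n <- nrow(fit$draws)
  idx <- if (n > max_gen) round(seq(1, n, length.out = max_gen)) else seq_len(n)
  nd <- length(idx)
  A1 <- model$config$A + 1L
  keys <- group_key(model$groups$area, model$groups$gender)
  qty <- c("i", "f", "r", "inc_prob", "prev", "mort_prob", "rem_prob")
  gen <- lapply(keys, function(k)
    stats::setNames(lapply(qty, function(q) matrix(NA_real_, nd, A1)), qty))
  names(gen) <- keys
  ll <- matrix(NA_real_, nd, nrow(model$data))
  for (s in seq_len(nd)) {
    pars <- unflatten(model, fit$draws[idx[s], ])
    rates <- model_rates(model, pars)
    probs <- model_outcome_probs(model, pars)
    for (k in keys) {
      gen[[k]]$i[s, ] <- rates[[k]]$i
      gen[[k]]$f[s, ] <- rates[[k]]$f
      gen[[k]]$r[s, ] <- rates[[k]]$r
      gen[[k]]$inc_prob[s, ] <- probs[[k]]$inc_prob
      gen[[k]]$prev[s, ] <- probs[[k]]$prev
      gen[[k]]$mort_prob[s, ] <- probs[[k]]$mort_prob
      gen[[k]]$rem_prob[s, ] <- probs[[k]]$rem_prob
    }
    ll[s, ] <- pointwise_loglik(model$data, probs, clamp = TRUE)
  }
  fit$gen <- gen
  fit$gen_index <- idx
  fit$loglik <- ll
  fit
}

#' @export
print.cr_fit <- function(x, ...) {
  cat("Illness-death model fit (engine: ", x$engine, ")\n", sep = "")
  cat("  ", nrow(x$draws), " draws over ", ncol(x$draws), " parameters\n",
      sep = "")
  if (x$engine == "sample")
    cat("  max split-Rhat ", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
        ", min ESS ", round(min(x$diagnostics$ess, na.rm = TRUE)), "\n",
        sep = "")
  invisible(x)
}

#' Posterior summaries of rates and outcome probabilities
#'
#' @param fit A \code{"cr_fit"} on a full model.
#' @param quantities Which quantities to summarise: any of \code{"i"},
#'   \code{"f"}, \code{"r"} (rates) and \code{"inc_prob"}, \code{"prev"},
#'   \code{"mort_prob"}, \code{"rem_prob"}.
#' @param probs Quantiles reported alongside the posterior median.
#' @return Data frame: area, gender, quantity, age, median, lower, upper
#'   (and \code{mode} for the Laplace engine).
#' @export
fit_summary <- function(fit, quantities = c("i", "f", "r", "inc_prob",
                                            "prev", "mort_prob", "rem_prob"),
                        probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "cr_fit"), !is.null(fit$gen))
  model <- fit$model
  mode_q <- NULL
  if (fit$engine == "laplace") {
    pars <- unflatten(model, fit$mode)
    rates <- model_rates(model, pars)
    op <- model_outcome_probs(model, pars)
    mode_q <- lapply(names(rates), function(k)
      list(i = rates[[k]]$i, f = rates[[k]]$f, r = rates[[k]]$r,
           inc_prob = op[[k]]$inc_prob, prev = op[[k]]$prev,
           mort_prob = op[[k]]$mort_prob, rem_prob = op[[k]]$rem_prob))
    names(mode_q) <- names(rates)
  }
  out <- list()
  for (g in seq_len(nrow(model$groups))) {
    k <- group_key(model$groups$area[g], model$groups$gender[g])
    for (q in quantities) {
      m <- fit$gen[[k]][[q]]
      df <- data.frame(
        area = model$groups$area[g], gender = model$groups$gender[g],
        quantity = q, age = 0:model$config$A,
        median = apply(m, 2, stats::median),
        lower = apply(m, 2, stats::quantile, probs[1]),
        upper = apply(m, 2, stats::quantile, probs[2]))
      if (!is.null(mode_q)) df$mode <- mode_q[[k]][[q]]
      out[[length(out) + 1]] <- df
    }
  }
  do.call(rbind, out)
}

#' Export posterior draws in long format
#'
#' @param fit A \code{"cr_fit"}.
#' @param path CSV file: columns chain, iteration, parameter, value.
#' @export
write_draws <- function(fit, path) {
  ch <- if (is.null(fit$chain)) rep(1L, nrow(fit$draws)) else fit$chain
  it <- if (is.null(fit$iteration)) seq_len(nrow(fit$draws)) else fit$iteration
  long <- data.frame(
    chain = rep(ch, ncol(fit$draws)),
    iteration = rep(it, ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
    value = as.vector(fit$draws))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
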