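# Analytic gradient of the log posterior on the unconstrained scale,
# computed by reverse-mode differentiation through the full pipeline:
# spline coefficients -> rate curves -> annual transition probabilities
# (closed-form matrix exponential) -> state-occupancy recursion -> outcome
# probabilities -> binomial log-likelihood, plus the analytic prior terms.
# Exact gradients make quasi-Newton mode-finding reliable on these strongly
# curved, badly scaled posteriors, where finite-difference gradients with a
# global step size break down.
#
# Models with calendar-time trends fall back to finite differences in the
# optimiser (the cohort pathway is not differentiated here).

model_log_post_grad <- function(model, theta) {
  pars <- unflatten(model, theta)
  cfg <- model$config
  gp <- rapply(model$skeleton, function(x) x * 0, how = "replace")
  obs <- model$obs
  A1 <- cfg$A + 1L

  for (g in seq_len(nrow(model$groups))) {
    rows <- obs$rows[[g]]
    if (!length(rows)) next
    beta_i <- beta_for_group(model, pars, "inc", g)
    beta_f <- beta_for_group(model, pars, "cf", g)
    fw_i <- curve_forward(beta_i, model$basis, cfg$inc)
    fw_f <- curve_forward(beta_f, model$basis, cfg$cf)
    rem <- switch(cfg$remission,
      none = list(rate = numeric(A1)),
      const = list(rate = rep(exp(pars$rem$logr), A1)),
      spline = {
        br <- c(pars$rem$beta[1, ], rate_lambda(model, pars, "rem") *
                  pars$rem$z[1, ])
        curve_forward(br, model$basis, cfg$rem)
      })
    gl <- group_loglik_grad(fw_i$rate, fw_f$rate, rem$rate,
                            obs$age1[rows], obs$col[rows],
                            obs$num[rows], obs$denom[rows])
    dbeta_i <- curve_backward(gl$di, fw_i, model$basis, cfg$inc)
    dbeta_f <- curve_backward(gl$df, fw_f, model$basis, cfg$cf)
    gp <- scatter_beta_grad(gp, model, pars, "inc", g, dbeta_i)
    gp <- scatter_beta_grad(gp, model, pars, "cf", g, dbeta_f)
    if (cfg$remission == "const")
      gp$rem$logr <- gp$rem$logr + exp(pars$rem$logr) * sum(gl$dr)
    if (cfg$remission == "spline") {
      dbr <- curve_backward(gl$dr, rem, model$basis, cfg$rem)
      gp <- scatter_beta_grad(gp, model, pars, "rem", g, dbr)
    }
  }
  gp <- add_prior_grad(gp, model, pars)
  stats::setNames(unlist(gp), model$par_names)
}

# forward pass of a rate curve: linear predictor on the clamped basis,
# exponential cap, optional cumulative (increasing) construction
curve_forward <- function(beta, basis, constraint) {
  G <- basis_clamped(basis, constraint$a_base)
  eta_raw <- drop(G %*% beta)
  capped <- eta_raw >= 23
  eta <- pmin(eta_raw, 23)
  ex <- exp(eta)
  if (!constraint$increasing)
    return(list(rate = ex, ex = ex, capped = capped, G = G,
                increasing = FALSE))
  at <- basis$ages >= constraint$a_base
  rate <- numeric(length(eta))
  rate[at] <- cumsum(ex[at])
  rate[!at] <- rate[which(at)[1]]
  list(rate = rate, ex = ex, capped = capped, G = G, at = at,
       increasing = TRUE)
}

# adjoint of curve_forward: d(loglik)/d(rate) -> d/d(beta)
curve_backward <- function(drate, fw, basis, constraint) {
  if (!fw$increasing) {
    deta <- fw$ex * drate
  } else {
    at <- fw$at
    dcum <- drate[at]
    dcum[1] <- dcum[1] + sum(drate[!at])
    dexp <- rev(cumsum(rev(dcum)))
    deta <- numeric(length(drate))
    deta[at] <- fw$ex[at] * dexp
  }
  deta[fw$capped] <- 0
  drop(crossprod(fw$G, deta))
}

# reverse-mode gradient of the binomial log-likelihood of one group's
# records with respect to the per-age rates (i, f, r)
group_loglik_grad <- function(i, f, r, age1, col, num, denom) {
  n <- length(i)
  cf <- expm2_coefs(i, f, r)
  c0 <- cf$c0; c1 <- cf$c1
  P11 <- clamp01(-i * c1 + c0)
  P12 <- clamp01(i * c1)
  P21 <- clamp01(r * c1)
  P22 <- clamp01(-(r + f) * c1 + c0)
  P13 <- pmax(1 - P11 - P12, 0)
  P23 <- pmax(1 - P21 - P22, 0)
  s1 <- numeric(n); s2 <- numeric(n)
  s1[1] <- 1
  for (a in seq_len(n - 1L)) {
    s1[a + 1L] <- s1[a] * P11[a] + s2[a] * P21[a]
    s2[a + 1L] <- s1[a] * P12[a] + s2[a] * P22[a]
  }
  alive <- s1 + s2
  ok <- alive > 1e-280
  src <- cummax(ifelse(ok, seq_len(n), 0L))
  src[src == 0L] <- which(ok)[1]
  pi_a <- (s2 / pmax(alive, 1e-300))[src]
  mort <- P23 * pi_a + P13 * (1 - pi_a)
  M <- cbind(1 - P11, pi_a, mort, P21)
  p <- pmin(pmax(M[cbind(age1, col)], 1e-300), 1 - 1e-15)
  dp <- ifelse(denom == 0L, 0, num / p - (denom - num) / (1 - p))
  dM <- matrix(0, n, 4)
  dM[cbind(age1, col)] <- dp
  dincp <- dM[, 1]; dpi_direct <- dM[, 2]; dmort <- dM[, 3]
  dremp <- dM[, 4]
  # mortality: d = P23 pi + P13 (1 - pi)
  dpi <- dpi_direct + dmort * (P23 - P13)
  dP23 <- dmort * pi_a
  dP13 <- dmort * (1 - pi_a)
  dP11 <- -dincp
  dP21 <- dremp
  dP12 <- numeric(n); dP22 <- numeric(n)
  # prevalence carried forward at extinct ages: credit the source age
  dpi_eff <- numeric(n)
  for (a in seq_len(n)) dpi_eff[src[a]] <- dpi_eff[src[a]] + dpi[a]
  # occupancy adjoint
  dpi1 <- ifelse(ok, -dpi_eff * s2 / alive^2, 0)
  dpi2 <- ifelse(ok,  dpi_eff * s1 / alive^2, 0)
  ds1 <- numeric(n); ds2 <- numeric(n)
  for (a in n:1) {
    ds1[a] <- ds1[a] + dpi1[a]
    ds2[a] <- ds2[a] + dpi2[a]
    if (a > 1L) {
      b <- a - 1L
      ds1[b] <- P11[b] * ds1[a] + P12[b] * ds2[a]
      ds2[b] <- P21[b] * ds1[a] + P22[b] * ds2[a]
      dP11[b] <- dP11[b] + s1[b] * ds1[a]
      dP12[b] <- dP12[b] + s1[b] * ds2[a]
      dP21[b] <- dP21[b] + s2[b] * ds1[a]
      dP22[b] <- dP22[b] + s2[b] * ds2[a]
    }
  }
  # absorb the row-sum entries: P13 = 1 - P11 - P12, P23 = 1 - P21 - P22
  dP11 <- dP11 - dP13
  dP12 <- dP12 - dP13
  dP21 <- dP21 - dP23
  dP22 <- dP22 - dP23
  # P entries -> (c0, c1) and direct rate terms
  dc1 <- -i * dP11 + i * dP12 + r * dP21 - (r + f) * dP22
  dc0 <- dP11 + dP22
  di <- c1 * (dP12 - dP11)
  dr <- c1 * (dP21 - dP22)
  df <- -c1 * dP22
  # (c0, c1) -> (u, v) -> rates
  du <- dc1 * cf$dc1du + dc0 * cf$dc0du
  dv <- dc1 * cf$dc1dv + dc0 * cf$dc0dv
  di <- di - du / 2 + dv * (i + r - f) / 2
  df <- df - du / 2 + dv * (r + f - i) / 2
  dr <- dr - du / 2 + dv * (i + r + f) / 2
  list(di = di, df = df, dr = dr)
}

# scatter d(loglik)/d(beta) for one group into the parameter blocks,
# reversing beta_for_group
scatter_beta_grad <- function(gp, model, pars, rate, g, dbeta) {
  cfg <- model$config
  K <- cfg$K
  area <- model$groups$area[g]
  gender <- model$groups$gender[g]
  unit <- if (rate == "rem") 1L
          else if (cfg$gender == "interaction") group_key(area, gender)
          else area
  lam <- rate_lambda(model, pars, rate)
  if (rate == "cf" && cfg$hierarchical) {
    lam1 <- if (!is.null(pars$cf$loglambda1)) exp(pars$cf$loglambda1)
            else cfg$fixed$lambda_area
    gp$cf$b1 <- gp$cf$b1 + dbeta[1]
    gp$cf$u[[unit]] <- gp$cf$u[[unit]] + lam1 * dbeta[1]
    if (!is.null(gp$cf$loglambda1))
      gp$cf$loglambda1 <- gp$cf$loglambda1 +
        lam1 * pars$cf$u[[unit]] * dbeta[1]
    gp$cf$b2 <- gp$cf$b2 + dbeta[2]
    gp$cf$z[unit, ] <- gp$cf$z[unit, ] + lam * dbeta[-(1:2)]
    if (!is.null(gp$cf$loglambda))
      gp$cf$loglambda <- gp$cf$loglambda +
        lam * sum(pars$cf$z[unit, ] * dbeta[-(1:2)])
  } else {
    gp[[rate]]$beta[unit, ] <- gp[[rate]]$beta[unit, ] + dbeta[1:2]
    gp[[rate]]$z[unit, ] <- gp[[rate]]$z[unit, ] + lam * dbeta[-(1:2)]
    if (!is.null(gp[[rate]]$loglambda))
      gp[[rate]]$loglambda <- gp[[rate]]$loglambda +
        lam * sum(pars[[rate]]$z[unit, ] * dbeta[-(1:2)])
  }
  if (cfg$gender == "additive" && gender == "male" &&
      !is.null(gp[[rate]]$male))
    gp[[rate]]$male <- gp[[rate]]$male + dbeta
  gp
}

# analytic gradient of the log prior (mirrors model_log_prior)
add_prior_grad <- function(gp, model, pars) {
  pr <- model$priors
  cfg <- model$config
  dnorm_g <- function(x, ms) -(x - ms[1]) / ms[2]^2
  # gamma prior + Jacobian on log(SD): d/dloglam = shape - rate * lambda
  dlam_g <- function(loglam, sr) sr[1] - sr[2] * exp(loglam)
  for (blk in c("inc", "cf", "rem")) {
    pb <- pars[[blk]]
    if (is.null(pb)) next
    if (!is.null(pb$beta)) {
      gp[[blk]]$beta[, 1] <- gp[[blk]]$beta[, 1] +
        dnorm_g(pb$beta[, 1], pr$intercept)
      gp[[blk]]$beta[, 2] <- gp[[blk]]$beta[, 2] +
        dnorm_g(pb$beta[, 2], pr$slope)
    }
    if (!is.null(pb$z)) gp[[blk]]$z <- gp[[blk]]$z - pb$z
    if (!is.null(pb$loglambda))
      gp[[blk]]$loglambda <- gp[[blk]]$loglambda +
        dlam_g(pb$loglambda, pr$lambda)
    if (!is.null(pb$male)) {
      gmale <- numeric(length(pb$male))
      gmale[1:2] <- dnorm_g(pb$male[1:2], c(0, pr$gender_sd))
      if (length(pb$male) > 2)
        gmale[-(1:2)] <- dnorm_g(pb$male[-(1:2)], c(0, pr$lambda_male))
      gp[[blk]]$male <- gp[[blk]]$male + gmale
    }
  }
  if (cfg$hierarchical) {
    gp$cf$u <- gp$cf$u - pars$cf$u
    gp$cf$b1 <- gp$cf$b1 + dnorm_g(pars$cf$b1, pr$b1)
    gp$cf$b2 <- gp$cf$b2 + dnorm_g(pars$cf$b2, pr$b2)
    if (!is.null(pars$cf$loglambda1))
      gp$cf$loglambda1 <- gp$cf$loglambda1 +
        dlam_g(pars$cf$loglambda1, pr$lambda_area)
  }
  if (cfg$remission == "const")
    gp$rem$logr <- gp$rem$logr + dnorm_g(pars$rem$logr, pr$intercept)
  gp
}
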