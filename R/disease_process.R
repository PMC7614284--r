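#' Intensity matrix of the illness-death model
#'
#' Builds the 3x3 matrix of instantaneous transition rates among the states
#' 1 = disease-free, 2 = disease, 3 = dead from the disease.  Death from the
#' disease without having the disease is impossible, and death is absorbing.
#'
#' @param i Incidence rate (per person-year), the rate of disease onset
#'   among the disease-free.
#' @param f Case fatality rate, the death rate among people with the disease.
#' @param r Remission rate, the rate of return to the disease-free state.
#'
#' @return A 3x3 matrix with rows summing to zero:
#'   \code{rbind(c(-i, i, 0), c(r, -(r+f), f), c(0, 0, 0))}.
#'
#' @examples
#' intensity_matrix(0.1, 0.2, 0.05)
#' @export
intensity_matrix <- function(i, f, r) {
  check_rate(i, "i")
  check_rate(f, "f")
  check_rate(r, "r")
  matrix(c(-i,      i,        0,
            r, -(r + f),      f,
            0,      0,        0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("healthy", "disease", "dead"),
                         c("healthy", "disease", "dead")))
}

check_rate <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x < 0)
    stop("rate '", name, "' must be a single finite nonnegative number, got ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  invisible(x)
}

#' Annual transition probability matrix
#'
#' The probability matrix P over one year of age, for rates held constant
#' within the year: P is the matrix exponential of the intensity matrix.
#' Because death is absorbing and unreachable from the healthy state except
#' through disease, the exponential has a closed form via the eigenvalues of
#' the upper-left 2x2 block, which is what is evaluated here (no iterative
#' approximation).
#'
#' @inheritParams intensity_matrix
#' @return A 3x3 row-stochastic matrix; entry (r, s) is the probability of
#'   being in state s at age a+1 given state r at age a.  Row 3 is (0,0,1).
#' @examples
#' annual_transition_probs(0.1, 0, 0)["healthy", "healthy"]  # exp(-0.1)
#' @export
annual_transition_probs <- function(i, f, r) {
  check_rate(i, "i")
  check_rate(f, "f")
  check_rate(r, "r")
  P <- transition_prob_array(i, f, r)[1, , ]
  dimnames(P) <- list(c("healthy", "disease", "dead"),
                      c("healthy", "disease", "dead"))
  P
}

# Vectorised closed-form exp(Q) for the illness-death intensity matrix.
# i, f, r are equal-length vectors; returns an array [n, 3, 3].
#
# The 2x2 block Q2 = [[-i, i], [r, -(r+f)]] has real eigenvalues
# u +/- sqrt(v), with u = -(i+r+f)/2 and v = ((i-r-f)^2 + 4ir)/4 >= 0, and
#   exp(Q2) = c1 Q2 + c0 I,
#   c1 = e^u sinh(sqrt(v))/sqrt(v),  c0 = e^u (cosh(sqrt(v)) - u c1/e^u).
# sinh(sqrt(v))/sqrt(v) and cosh(sqrt(v)) are analytic functions of v, so
# this form is smooth through the coincident-eigenvalue case v = 0 (handled
# by series expansion), which matters for derivative-based inference.
transition_prob_array <- function(i, f, r) {
  n <- length(i)
  stopifnot(length(f) == n, length(r) == n)
  cf <- expm2_coefs(i, f, r)
  c0 <- cf$c0
  c1 <- cf$c1
  P <- array(0, dim = c(n, 3, 3))
  P[, 1, 1] <- clamp01(c1 * (-i) + c0)
  P[, 1, 2] <- clamp01(c1 * i)
  P[, 2, 1] <- clamp01(c1 * r)
  P[, 2, 2] <- clamp01(c1 * (-(r + f)) + c0)
  P[, 1, 3] <- pmax(1 - P[, 1, 1] - P[, 1, 2], 0)
  P[, 2, 3] <- pmax(1 - P[, 2, 1] - P[, 2, 2], 0)
  P[, 3, 3] <- 1
  P
}

# Coefficients of exp(Q2) = c1 Q2 + c0 I and their partial derivatives in
# u = -(i+r+f)/2 and v = ((i-r-f)^2 + 4ir)/4:
#   c1 = e^u sinh(w)/w,  ech = e^u cosh(w),  c0 = ech - u c1,  w = sqrt(v).
# Both eigenvalues u +/- w are <= 0, so the large-w branch exponentiates
# them directly (no overflow); the small-v branch uses the series of the
# analytic functions sinh(w)/w and cosh(w) in v.
expm2_coefs <- function(i, f, r) {
  u <- -(i + r + f) / 2
  v <- ((i - r - f)^2 + 4 * i * r) / 4
  small <- v < 1e-6
  w <- sqrt(pmax(v, 1e-300))
  e1 <- exp(u + w)
  e2 <- exp(u - w)
  eu <- exp(u)
  c1 <- ifelse(small, eu * (1 + v / 6 + v^2 / 120), (e1 - e2) / (2 * w))
  ech <- ifelse(small, eu * (1 + v / 2 + v^2 / 24), (e1 + e2) / 2)
  c0 <- ech - u * c1
  dc1dv <- ifelse(small, eu * (1 / 6 + v / 30),
                  (ech - c1) / (2 * pmax(v, 1e-300)))
  list(u = u, v = v, c0 = c0, c1 = c1,
       dc1du = c1, dc1dv = dc1dv,
       dc0du = c0 - c1, dc0dv = c1 / 2 - u * dc1dv)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Rate schedule: per-age transition rates
#'
#' The estimand of the whole package: incidence, case fatality and remission
#' rates for each integer year of age 0..A, assumed piecewise constant
#' within years of age.
#'
#' @param i,f,r Numeric vectors of length A+1: incidence, case fatality and
#'   remission rates per person-year at ages 0..A.  All finite and >= 0.
#' @return An object of class \code{"rate_schedule"}: a list with elements
#'   \code{ages}, \code{i}, \code{f}, \code{r}.
#' @export
rate_schedule <- function(i, f, r = rep(0, length(i))) {
  A <- length(i) - 1L
  if (length(f) != A + 1L || length(r) != A + 1L)
    stop("i, f, r must share a common length A+1", call. = FALSE)
  for (nm in c("i", "f", "r")) {
    x <- get(nm)
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
      stop("rates '", nm, "' must be finite and nonnegative", call. = FALSE)
  }
  structure(list(ages = 0:A, i = as.numeric(i), f = as.numeric(f),
                 r = as.numeric(r)),
            class = "rate_schedule")
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat("Rate schedule over ages 0..", max(x$ages), "\n", sep = "")
  show <- x$ages %in% round(seq(0, max(x$ages), length.out = 6))
  print(data.frame(age = x$ages, incidence = signif(x$i, 4),
                   case_fatality = signif(x$f, 4),
                   remission = signif(x$r, 4))[show, ], row.names = FALSE)
  invisible(x)
}

#' State occupancy probabilities of a hypothetical birth cohort
#'
#' Runs the occupancy recursion S_{a+1} = S_a P_a from a fixed starting
#' vector, where P_a is the annual transition probability matrix for the
#' rates at age a.
#'
#' @param rates A \code{\link{rate_schedule}}.
#' @param S0 Length-3 probability vector at age 0; the default assumes
#'   everyone disease-free at birth.  Override for conditions present at
#'   birth.
#' @return A (A+1) x 3 matrix; row a+1 is the probability of occupying
#'   (healthy, disease, dead) at age a.
#' @export
state_occupancy <- function(rates, S0 = c(1, 0, 0)) {
  stopifnot(inherits(rates, "rate_schedule"))
  if (length(S0) != 3 || any(S0 < 0) || abs(sum(S0) - 1) > 1e-8)
    stop("S0 must be a length-3 probability vector summing to 1",
         call. = FALSE)
  A <- length(rates$i) - 1L
  P <- transition_prob_array(rates$i, rates$f, rates$r)
  S <- matrix(0, A + 1L, 3, dimnames = list(NULL, c("healthy", "disease", "dead")))
  S[1L, ] <- S0
  for (a in seq_len(A))
    S[a + 1L, ] <- S[a, ] %*% P[a, , ]
  S
}

#' Prevalence among the living
#'
#' @param S_a Length-3 occupancy vector (healthy, disease, dead), or a
#'   matrix of such rows.
#' @return The proportion with disease among those alive,
#'   S2 / (S1 + S2).
#' @export
prevalence <- function(S_a) {
  if (is.matrix(S_a)) return(unname(apply(S_a, 1, prevalence)))
  alive <- S_a[1] + S_a[2]
  if (alive <= 0)
    stop("prevalence undefined: no probability of being alive", call. = FALSE)
  unname(S_a[2] / alive)
}

#' Annual disease-specific mortality probability
#'
#' The probability that a person alive at age a dies from the disease before
#' age a+1: a prevalence-weighted mixture of the death probabilities from the
#' disease and healthy states, d_a = P23 * pi + P13 * (1 - pi).
#'
#' @param P_a 3x3 annual transition probability matrix at age a.
#' @param pi_a Prevalence among the living at age a.
#' @export
mortality_prob <- function(P_a, pi_a) {
  stopifnot(is.matrix(P_a), all(dim(P_a) == 3))
  if (!is.numeric(pi_a) || pi_a < 0 || pi_a > 1)
    stop("pi_a must be a probability", call. = FALSE)
  P_a[2, 3] * pi_a + P_a[1, 3] * (1 - pi_a)
}

#' Outcome probabilities generated by a rate schedule
#'
#' The deterministic bridge from transition rates to the four observable
#' outcome probabilities at every age: the annual incidence probability
#' 1 - P11, the prevalence among the living, the population disease-specific
#' mortality probability, and the annual remission probability P21.
#'
#' If the hypothetical cohort dies out numerically at old ages (the living
#' probability underflows), the last well-defined prevalence is carried
#' forward and the affected ages are reported in the \code{"carried"}
#' attribute.
#'
#' @inheritParams state_occupancy
#' @return A data frame with one row per age 0..A and columns \code{age},
#'   \code{inc_prob}, \code{prev}, \code{mort_prob}, \code{rem_prob}.
#' @examples
#' rs <- rate_schedule(i = rep(0.01, 61), f = rep(0.1, 61))
#' head(outcome_probabilities(rs))
#' @export
outcome_probabilities <- function(rates, S0 = c(1, 0, 0)) {
  stopifnot(inherits(rates, "rate_schedule"))
  P <- transition_prob_array(rates$i, rates$f, rates$r)
  S <- state_occupancy(rates, S0)
  outcome_probs_from_PS(P, S, rates$ages)
}

# Lean internal path used inside likelihood evaluations: outcome
# probabilities as a plain (A+1) x 4 matrix (inc_prob, prev, mort_prob,
# rem_prob) with no validation, class dispatch or data-frame construction.
# Underflow of the living probability carries the last defined prevalence
# forward silently; the exported wrappers report it.
outcome_prob_mat <- function(i, f, r, S0 = c(1, 0, 0)) {
  P <- transition_prob_array(i, f, r)
  n <- length(i)
  P11 <- P[, 1, 1]; P12 <- P[, 1, 2]; P21 <- P[, 2, 1]; P22 <- P[, 2, 2]
  s1 <- S0[1]; s2 <- S0[2]
  pi_a <- numeric(n)
  prev_last <- if (s1 + s2 > 0) s2 / (s1 + s2) else 0
  for (a in seq_len(n)) {
    alive <- s1 + s2
    if (alive > 1e-280) prev_last <- s2 / alive
    pi_a[a] <- prev_last
    t1 <- s1 * P11[a] + s2 * P21[a]
    s2 <- s1 * P12[a] + s2 * P22[a]
    s1 <- t1
  }
  cbind(1 - P11, pi_a, P[, 2, 3] * pi_a + P[, 1, 3] * (1 - pi_a), P21)
}

# shared by the trend and no-trend pathways: P is [n,3,3] of the matrices
# applying at the data year, S the occupancy at each age.
outcome_probs_from_PS <- function(P, S, ages) {
  alive <- S[, 1] + S[, 2]
  ok <- alive > .Machine$double.xmin * 1e20
  pi_a <- numeric(length(ages))
  if (!ok[1] && all(S[1, 1:2] == 0))
    stop("initial state has no probability of being alive", call. = FALSE)
  last <- if (ok[1]) S[1, 2] / alive[1] else 0
  for (a in seq_along(ages)) {
    if (ok[a]) last <- S[a, 2] / alive[a]
    pi_a[a] <- last
  }
  carried <- ages[!ok]
  if (length(carried))
    message("prevalence carried forward at ages ",
            paste(carried, collapse = ","),
            " (cohort numerically extinct)")
  out <- data.frame(
    age       = ages,
    inc_prob  = 1 - P[, 1, 1],
    prev      = pi_a,
    mort_prob = P[, 2, 3] * pi_a + P[, 1, 3] * (1 - pi_a),
    rem_prob  = P[, 2, 1]
  )
  attr(out, "carried") <- carried
  out
}
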