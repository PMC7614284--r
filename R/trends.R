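#' Calendar-time trend matrix
#'
#' Published time trends enter the model as known age-by-year risk ratios:
#' entry (a, y) is the ratio of the rate at age a in calendar year y to the
#' rate at age a in the year of the data.  Years are indexed 0..100 with
#' y = 100 the year of the data, so the ratios in the final column must all
#' equal 1 (the current-year rates are the estimands themselves).
#'
#' Years missing from the supplied grid are filled: years earlier than the
#' first supplied year carry the earliest column backward, later years carry
#' the last column forward, and interior gaps are interpolated linearly on
#' the log-ratio scale.
#'
#' @param values Matrix of positive ratios with rows = ages 0..A.  Columns
#'   correspond to \code{years}.
#' @param years Integer year offsets (0..100) labelling the columns of
#'   \code{values}.  Must include 100, with ratio 1 at every age, or 100 is
#'   appended as a column of ones.
#' @param A Maximum age; the returned matrix has A+1 rows.
#' @return A (A+1) x 101 matrix of class \code{"trend_matrix"}.
#' @export
trend_matrix <- function(values, years = seq_len(ncol(values)) - 1L, A = nrow(values) - 1L) {
  values <- as.matrix(values)
  if (nrow(values) < A + 1L)
    stop("trend grid has ", nrow(values), " age rows; need ages 0..", A,
         call. = FALSE)
  values <- values[seq_len(A + 1L), , drop = FALSE]
  if (length(years) != ncol(values))
    stop("length(years) must match ncol(values)", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("trend ratios must all be positive and finite", call. = FALSE)
  o <- order(years)
  years <- as.integer(years[o])
  values <- values[, o, drop = FALSE]
  if (any(duplicated(years)) || any(years < 0) || any(years > 100))
    stop("years must be distinct offsets in 0..100", call. = FALSE)
  if (!100L %in% years) {
    years <- c(years, 100L)
    values <- cbind(values, 1)
  }
  if (any(abs(values[, years == 100L] - 1) > 1e-8))
    stop("ratios in the data year (y = 100) must all equal 1", call. = FALSE)
  full <- matrix(NA_real_, A + 1L, 101L)
  for (a in seq_len(A + 1L)) {
    lv <- stats::approx(years, log(values[a, ]), xout = 0:100, rule = 2)$y
    full[a, ] <- exp(lv)
  }
  dimnames(full) <- list(age = 0:A, year = 0:100)
  structure(full, class = c("trend_matrix", "matrix"))
}

#' Read a trend matrix from CSV
#'
#' The file holds one row per age 0..A and one column per year offset; column
#' names are the year offsets (optionally prefixed, e.g. \code{y0}, or an
#' \code{age} column which is checked and dropped).
#'
#' @param path CSV file path.
#' @param A Maximum age.
#' @export
read_trend_matrix <- function(path, A = 100) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  if ("age" %in% nm) {
    if (!identical(as.integer(df$age), 0:(nrow(df) - 1L)))
      stop("'age' column in ", path, " must run 0..A in order", call. = FALSE)
    df <- df[setdiff(nm, "age")]
  }
  years <- suppressWarnings(as.integer(gsub("[^0-9]", "", names(df))))
  if (any(is.na(years)))
    stop("column names of ", path, " must encode year offsets", call. = FALSE)
  trend_matrix(as.matrix(df), years = years, A = A)
}

#' Outcome probabilities under calendar-time trends
#'
#' Computes the outcome probabilities for the year of the data when past
#' incidence and case-fatality rates differed from current ones by known
#' ratios.  Each birth cohort is pushed forward through its own
#' calendar-year-specific transition probabilities: the occupancy of the
#' cohort aged a in the data year is built from rates
#' i_{b,y} = rho_i[b, y] * i_b and f_{b,y} = rho_f[b, y] * f_b at
#' (b, y) = (0, 100-a), ..., (a-1, 99).  Remission is assumed free of
#' trends.  With both ratio matrices identically 1 this reduces exactly to
#' \code{\link{outcome_probabilities}}.
#'
#' @inheritParams state_occupancy
#' @param trend_i,trend_f \code{\link{trend_matrix}} objects for incidence
#'   and case fatality (default: no trend).
#' @return As \code{\link{outcome_probabilities}}.
#' @export
cohort_outcome_probabilities <- function(rates, trend_i = NULL, trend_f = NULL,
                                         S0 = c(1, 0, 0)) {
  stopifnot(inherits(rates, "rate_schedule"))
  A <- length(rates$i) - 1L
  if (is.null(trend_i) && is.null(trend_f))
    return(outcome_probabilities(rates, S0))
  one <- matrix(1, A + 1L, 101L)
  rho_i <- if (is.null(trend_i)) one else unclass(trend_i)
  rho_f <- if (is.null(trend_f)) one else unclass(trend_f)
  for (rho in list(rho_i, rho_f))
    if (nrow(rho) < A + 1L)
      stop("trend grid covers fewer ages than the rate schedule",
           call. = FALSE)
  if (length(S0) != 3 || any(S0 < 0) || abs(sum(S0) - 1) > 1e-8)
    stop("S0 must be a length-3 probability vector summing to 1",
         call. = FALSE)

  # occupancy at the data year for the cohort currently aged a: apply the
  # age-b matrix at year 100 - a + b for b = 0..a-1
  S <- matrix(0, A + 1L, 3)
  S[1L, ] <- S0
  for (a in seq_len(A)) {
    b <- 0:(a - 1L)
    y <- 100L - a + b
    Pc <- transition_prob_array(rates$i[b + 1L] * rho_i[cbind(b + 1L, y + 1L)],
                                rates$f[b + 1L] * rho_f[cbind(b + 1L, y + 1L)],
                                rates$r[b + 1L])
    s <- S0
    for (k in seq_along(b))
      s <- s %*% Pc[k, , ]
    S[a + 1L, ] <- s
  }
  # outcome probabilities at the data year use the current-year matrices
  # (the ratios at y = 100 are 1 by construction)
  P <- transition_prob_array(rates$i, rates$f, rates$r)
  outcome_probs_from_PS(P, S, rates$ages)
}
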