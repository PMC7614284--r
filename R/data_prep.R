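#' Convert a published estimate with 95\% interval to equivalent counts
#'
#' Published probabilities with interval bounds are converted to an
#' approximately equivalent binomial numerator and denominator: the (y, n)
#' whose Jeffreys-style Beta(y + 0.5, n - y + 0.5) 95\% interval best
#' matches the published bounds in squared error, with y = round(est * n).
#' The match is tolerance-based, not exact: the published intervals rarely
#' arise from an actual binomial experiment.
#'
#' @param est Point estimate in [0, 1].
#' @param lower,upper Published 95\% interval bounds,
#'   0 <= lower <= est <= upper <= 1, with upper > lower.
#' @param max_n Largest denominator considered.
#' @return List with integer \code{num} and \code{denom} (denom >= 1), and
#'   the achieved interval \code{lower}, \code{upper}.
#' @examples
#' counts_from_estimate(0.5, qbeta(0.025, 50.5, 50.5), qbeta(0.975, 50.5, 50.5))
#' @export
counts_from_estimate <- function(est, lower, upper, max_n = 1e7) {
  if (any(!is.finite(c(est, lower, upper))) ||
      lower < 0 || upper > 1)
    stop("est, lower, upper must be probabilities", call. = FALSE)
  if (est < lower || est > upper)
    stop("estimate ", est, " lies outside its interval [", lower, ", ",
         upper, "]", call. = FALSE)
  if (upper <= lower)
    stop("zero-width interval: supply a denominator directly instead of ",
         "inverting an interval", call. = FALSE)
  sse <- function(n) {
    y <- round(est * n)
    b <- stats::qbeta(c(0.025, 0.975), y + 0.5, n - y + 0.5)
    (b[1] - lower)^2 + (b[2] - upper)^2
  }
  # coarse log-spaced scan, then refine around the best candidate
  grid <- unique(pmax(round(exp(seq(log(1), log(max_n), length.out = 300))), 1))
  best <- grid[which.min(vapply(grid, sse, 0))]
  local <- unique(pmax(round(seq(best / 1.6, best * 1.6, length.out = 200)), 1))
  best <- local[which.min(vapply(local, sse, 0))]
  fine <- unique(pmax(seq(best - 25, best + 25), 1))
  n <- fine[which.min(vapply(fine, sse, 0))]
  y <- round(est * n)
  b <- stats::qbeta(c(0.025, 0.975), y + 0.5, n - y + 0.5)
  list(num = as.integer(y), denom = as.integer(n),
       lower = b[1], upper = b[2])
}

#' Convert an estimate-format table to count data
#'
#' Applies \code{\link{counts_from_estimate}} to each row and
#' \code{\link{disaggregate_age_groups}} within each (area, gender, measure)
#' series, returning single-year-of-age counts.
#'
#' @param df Data frame with columns \code{agegroup_start},
#'   \code{agegroup_end} (half-open interval), \code{measure}, \code{est},
#'   \code{lower}, \code{upper}, and optionally \code{area}, \code{gender}.
#' @param A Terminal age at which an open-ended last group is closed.
#' @return A \code{\link{count_data}} data frame by single year of age.
#' @export
estimates_to_counts <- function(df, A = 100) {
  need <- c("agegroup_start", "agegroup_end", "measure", "est", "lower",
            "upper")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("estimate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"area" %in% names(df)) df$area <- "all"
  if (!"gender" %in% names(df)) df$gender <- "all"
  df$agegroup_end <- pmin(df$agegroup_end, A + 1)
  out <- list()
  for (a in unique(df$area)) for (g in unique(df$gender))
    for (m in unique(df$measure)) {
      sub <- df[df$area == a & df$gender == g & df$measure == m, ,
                drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(sub$agegroup_start), , drop = FALSE]
      cnt <- t(vapply(seq_len(nrow(sub)), function(r) {
        cc <- counts_from_estimate(sub$est[r], sub$lower[r], sub$upper[r])
        c(cc$num, cc$denom)
      }, numeric(2)))
      yearly <- disaggregate_age_groups(data.frame(
        start = sub$agegroup_start, end = sub$agegroup_end,
        num = cnt[, 1], denom = cnt[, 2]))
      out[[length(out) + 1]] <- data.frame(
        area = a, gender = g, age = yearly$age, measure = m,
        num = yearly$num, denom = yearly$denom)
    }
  count_data(do.call(rbind, out))
}

#' Disaggregate age-group counts to single years of age
#'
#' Splits counts for coarse age groups into smoothly varying single-year
#' counts that sum exactly to each group total.  A penalised composite-link
#' model is used: latent log yearly counts with a second-order difference
#' penalty, fitted to the group totals by penalised Poisson scoring, with
#' the penalty weight chosen by AIC over a log-spaced grid.  Numerators and
#' denominators are disaggregated with the same machinery so the implied
#' yearly proportions vary smoothly.  Yearly values are rounded to integers
#' by largest-remainder apportionment within each group, so group totals
#' are conserved exactly.
#'
#' @param groups Data frame with columns \code{start}, \code{end} (half-open
#'   intervals [start, end), contiguous and non-overlapping), \code{num},
#'   \code{denom}.
#' @return Data frame with columns \code{age}, \code{num}, \code{denom},
#'   one row per year of age from \code{min(start)} to \code{max(end) - 1}.
#' @export
disaggregate_age_groups <- function(groups) {
  need <- c("start", "end", "num", "denom")
  if (!all(need %in% names(groups)))
    stop("groups needs columns start, end, num, denom", call. = FALSE)
  groups <- groups[order(groups$start), , drop = FALSE]
  if (any(groups$end <= groups$start))
    stop("age groups must be nonempty half-open intervals", call. = FALSE)
  if (nrow(groups) > 1 &&
      any(groups$start[-1] != groups$end[-nrow(groups)]))
    stop("age groups must be contiguous and non-overlapping", call. = FALSE)
  ages <- seq(min(groups$start), max(groups$end) - 1)
  gidx <- findInterval(ages, groups$start)
  C <- outer(seq_len(nrow(groups)), gidx, `==`) * 1
  denom <- apportion(pclm_smooth(groups$denom, C), groups$denom, gidx)
  num <- apportion(pclm_smooth(groups$num, C), groups$num, gidx)
  num <- pmin(num, denom)
  # capping at the denominator can lose numerator mass: restore within group
  for (g in seq_len(nrow(groups))) {
    at <- which(gidx == g)
    short <- groups$num[g] - sum(num[at])
    while (short > 0) {
      room <- at[num[at] < denom[at]]
      if (!length(room)) break
      take <- room[order(denom[room] - num[room], decreasing = TRUE)]
      take <- take[seq_len(min(short, length(take)))]
      num[take] <- num[take] + 1L
      short <- groups$num[g] - sum(num[at])
    }
  }
  data.frame(age = ages, num = num, denom = denom)
}

# penalised composite-link fit: group totals y, composition matrix C
# (groups x years); returns positive yearly values summing approximately to
# the group totals (exact conservation is applied afterwards)
pclm_smooth <- function(y, C, lambdas = 10^seq(-2, 6, by = 0.5)) {
  nx <- ncol(C)
  if (sum(y) == 0) return(numeric(nx))
  if (nx <= 2) return(rep(sum(y) / nx, nx))
  D <- diff(diag(nx), differences = min(2, nx - 1))
  DtD <- crossprod(D)
  fit_one <- function(lambda) {
    b <- rep(log(sum(y) / nx), nx)
    P <- lambda * DtD
    for (it in 1:100) {
      gam <- exp(b)
      mu <- drop(C %*% gam)
      mu <- pmax(mu, 1e-10)
      Gm <- C * rep(gam, each = nrow(C))      # d mu / d b
      w <- 1 / mu
      z <- (y - mu) + drop(Gm %*% b)
      QWQ <- crossprod(Gm, w * Gm)
      bnew <- tryCatch(
        solve(QWQ + P + diag(1e-10, nx), crossprod(Gm, w * z)),
        error = function(e) NULL)
      if (is.null(bnew)) return(NULL)
      if (max(abs(bnew - b)) < 1e-8) { b <- drop(bnew); break }
      b <- drop(bnew)
    }
    gam <- exp(b)
    mu <- pmax(drop(C %*% gam), 1e-10)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    H <- tryCatch(solve(QWQ + P + diag(1e-10, nx), QWQ),
                  error = function(e) NULL)
    if (is.null(H)) return(NULL)
    list(gam = gam, aic = dev + 2 * sum(diag(H)))
  }
  best <- NULL
  for (lam in lambdas) {
    f <- fit_one(lam)
    if (!is.null(f) && (is.null(best) || f$aic < best$aic)) best <- f
  }
  if (is.null(best))
    stop("composite-link disaggregation failed to converge", call. = FALSE)
  best$gam
}

# largest-remainder rounding of smooth yearly values to integers matching
# each group total exactly
apportion <- function(values, totals, gidx) {
  out <- integer(length(values))
  for (g in seq_along(totals)) {
    at <- which(gidx == g)
    v <- values[at]
    if (sum(v) <= 0) v <- rep(1, length(at))
    share <- v / sum(v) * totals[g]
    fl <- floor(share)
    rem <- totals[g] - sum(fl)
    if (rem > 0) {
      extra <- order(share - fl, decreasing = TRUE)[seq_len(rem)]
      fl[extra] <- fl[extra] + 1
    }
    out[at] <- as.integer(fl)
  }
  out
}

#' Annual remission probability from a 10-year survival probability
#'
#' Under the convention that surviving a cancer for 10 years means remission
#' occurred within those 10 years, a 10-year survival probability s10
#' satisfies s10 = 1 - (1 - r)^10 for an annual remission probability r,
#' giving r = 1 - (1 - s10)^(1/10).
#'
#' @param s10 10-year survival probability in [0, 1] (vectorised).
#' @return Annual remission probability.
#' @examples
#' remission_from_survival(1 - 0.9^10)   # 0.1
#' @export
remission_from_survival <- function(s10) {
  if (any(!is.finite(s10)) || any(s10 < 0 | s10 > 1))
    stop("s10 must lie in [0, 1]", call. = FALSE)
  1 - (1 - s10)^(1 / 10)
}

#' Aggregate count data over areas
#'
#' Sums numerators and denominators within each (region, gender, age,
#' measure) after mapping areas to regions.
#'
#' @param data A \code{\link{count_data}} data frame.
#' @param mapping Named character vector: names are areas in the data,
#'   values the regions they aggregate into.
#' @return A \code{\link{count_data}} data frame with \code{area} holding
#'   the regions.
#' @export
aggregate_areas <- function(data, mapping) {
  data <- count_data(data)
  unmapped <- setdiff(unique(data$area), names(mapping))
  if (length(unmapped))
    stop("unmapped area(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  data$area <- unname(mapping[data$area])
  agg <- stats::aggregate(cbind(num, denom) ~ area + gender + age + measure,
                          data = data, FUN = sum)
  count_data(agg[order(agg$area, agg$gender, agg$measure, agg$age), ])
}
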