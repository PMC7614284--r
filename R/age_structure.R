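#' Thin-plate spline basis over age
#'
#' Constructs the K-column basis used for all log-rate age curves.  Age is
#' scaled to [0, 1] (divided by the maximum age) before construction so that
#' coefficient priors are on a sensible scale: a slope coefficient then
#' measures the change in log rate across the whole age span, not per year.
#'
#' Columns 1 and 2 are the intercept (all ones) and the scaled age.  The
#' remaining K-2 columns are the penalised part of a thin-plate regression
#' spline in its natural parameterisation, in which the smoothness penalty is
#' the identity, so that giving the corresponding coefficients exchangeable
#' Normal(0, lambda0^2) priors is equivalent to the thin-plate smoothness
#' prior with smoothing standard deviation lambda0.  These columns are
#' residualised against the intercept and linear columns, so a coefficient
#' vector that is zero beyond the first two entries yields a curve exactly
#' affine in age.
#'
#' @param ages Integer vector of ages (need not start at 0, but model
#'   construction uses 0..A).
#' @param K Number of basis columns, at least 3 and at most the number of
#'   distinct ages.  The default 10 gives high flexibility; the fitted
#'   smoothness prior shrinks unneeded flexibility away.
#' @return An object of class \code{"spline_basis"}: list with the basis
#'   matrix \code{G} (rows in the order of \code{ages}), \code{K},
#'   \code{ages}, and the age \code{scale} divisor.
#' @examples
#' b <- thinplate_basis(0:100, K = 10)
#' qr(b$G)$rank
#' @export
thinplate_basis <- function(ages, K = 10) {
  ages <- as.integer(ages)
  nd <- length(unique(ages))
  if (K < 3) stop("K must be at least 3", call. = FALSE)
  if (nd < K)
    stop("basis needs at least K = ", K, " distinct ages, got ", nd,
         call. = FALSE)
  scale <- max(ages)
  x <- ages / scale
  sm <- mgcv::smoothCon(mgcv::s(x, k = K, bs = "tp"),
                        data = data.frame(x = x),
                        absorb.cons = FALSE, diagonal.penalty = TRUE)[[1]]
  # natural parameterisation: penalised columns first, then linear, then
  # constant; reorder to (constant, linear, penalised) and normalise the
  # null-space columns to (1, x)
  X <- sm$X
  pen <- seq_len(K - 2)
  lin <- cbind(1, x)
  wig <- X[, pen, drop = FALSE]
  wig <- wig - lin %*% qr.solve(lin, wig)      # orthogonal to affine part
  G <- cbind(1, x, wig)
  colnames(G) <- paste0("g", seq_len(K))
  structure(list(G = G, K = K, ages = ages, scale = scale),
            class = "spline_basis")
}

#' Evaluate an age curve from spline coefficients
#'
#' Maps a coefficient vector to a positive per-age rate curve,
#' rate_a = exp(sum_k beta_k g_k(a)), with two optional structural
#' constraints:
#' \itemize{
#'   \item \code{a_base}: rates below this age are held constant at the
#'     value at \code{a_base} (the basis is evaluated at
#'     \code{max(age, a_base)});
#'   \item \code{increasing}: the spline models log increments instead of
#'     log rates, so the curve is the cumulative sum of exponentials from
#'     \code{a_base} upward, anchored at
#'     rate_{a_base} = exp(s(a_base)); such curves are nondecreasing for
#'     every coefficient vector.
#' }
#'
#' @param beta Coefficient vector of length \code{basis$K}.
#' @param basis A \code{\link{thinplate_basis}}.
#' @param a_base Age below which the rate is constant (default 0: no
#'   constraint).
#' @param increasing Logical; constrain the curve to be nondecreasing for
#'   ages at or above \code{a_base}.
#' @return Numeric vector of rates, one per age of the basis.
#' @examples
#' b <- thinplate_basis(0:100)
#' rate_curve(c(log(0.2), rep(0, 9)), b)[1]   # flat curve at 0.2
#' @export
rate_curve <- function(beta, basis, a_base = 0, increasing = FALSE) {
  stopifnot(inherits(basis, "spline_basis"))
  if (length(beta) != basis$K)
    stop("beta has length ", length(beta), " but the basis has K = ",
         basis$K, " columns", call. = FALSE)
  if (a_base < 0 || a_base > max(basis$ages))
    stop("a_base must lie within the age range", call. = FALSE)
  G <- basis_clamped(basis, a_base)
  # cap the log rate so extreme coefficient values (visited by unconstrained
  # optimisers and samplers) yield huge-but-finite rates rather than Inf
  eta <- pmin(drop(G %*% beta), 23)
  if (!increasing) return(exp(eta))
  # log-increment parameterisation: cumulative over ages >= a_base
  out <- numeric(length(eta))
  at <- basis$ages >= a_base
  out[at] <- cumsum(exp(eta[at]))
  out[!at] <- out[which(at)[1]]
  out
}

# basis rows with ages clamped below at a_base
basis_clamped <- function(basis, a_base) {
  if (a_base <= min(basis$ages)) return(basis$G)
  idx <- match(pmax(basis$ages, a_base), basis$ages)
  basis$G[idx, , drop = FALSE]
}

#' Export a basis matrix to CSV (debugging aid)
#' @param basis A \code{\link{thinplate_basis}}.
#' @param path Output file.
#' @export
write_basis <- function(basis, path) {
  utils::write.csv(data.frame(age = basis$ages, basis$G), path,
                   row.names = FALSE)
  invisible(path)
}
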