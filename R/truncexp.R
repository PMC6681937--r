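#' Truncated-exponential food-transfer distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the exponential distribution with scale `delta` truncated to the unit
#' interval. This is the distribution of the realised transfer fraction
#' \eqn{\tilde v = v / v_{max}} in a trophallactic interaction: the density is
#' \deqn{p_\delta(\tilde v) = \frac{c_\delta}{\delta} e^{-\tilde v/\delta},
#'   \qquad 0 \le \tilde v \le 1,}
#' with normaliser \eqn{c_\delta = 1/(1 - e^{-1/\delta})}. Small `delta` means
#' ants typically transfer a small fraction of the maximal feasible volume;
#' as `delta` grows without bound the density flattens to uniform on
#' \eqn{[0, 1]}.
#'
#' @param x,q vector of transfer fractions.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param delta scale parameter, > 0.
#' @return `dtruncexp` gives the density, `ptruncexp` the CDF, `qtruncexp` the
#'   quantile function and `rtruncexp` random draws, all on \eqn{[0, 1]}.
#' @examples
#' integrate(dtruncexp, 0, 1, delta = 0.26)$value  # 1
#' mean(rtruncexp(1e4, 0.26))
#' @export
dtruncexp <- function(x, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  c_delta <- 1 / (1 - exp(-1 / delta))
  out <- c_delta / delta * exp(-x / delta)
  out[x < 0 | x > 1] <- 0
  out
}

#' @rdname dtruncexp
#' @export
ptruncexp <- function(q, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  c_delta <- 1 / (1 - exp(-1 / delta))
  out <- c_delta * (1 - exp(-q / delta))
  out[q < 0] <- 0
  out[q > 1] <- 1
  out
}

#' @rdname dtruncexp
#' @export
qtruncexp <- function(p, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  -delta * log(1 - p * (1 - exp(-1 / delta)))
}

#' @rdname dtruncexp
#' @export
rtruncexp <- function(n, delta) {
  qtruncexp(stats::runif(n), delta)
}

#' Mean of the truncated-exponential transfer rule
#'
#' Closed-form mean of the unit-truncated exponential,
#' \eqn{E[\tilde v] = \delta - e^{-1/\delta} / (1 - e^{-1/\delta})}. Increases
#' monotonically in `delta` and approaches 1/2 as `delta` grows: sample means
#' at or above 1/2 are outside the family (uniform limit).
#'
#' @param delta scale parameter, > 0.
#' @return the expected transfer fraction, in \eqn{(0, 1/2)}.
#' @export
truncexp_mean <- function(delta) {
  delta - exp(-1 / delta) / (1 - exp(-1 / delta))
}
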