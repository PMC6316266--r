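#' Weibull probability density of the pitting parameter
#'
#' Density of the two-parameter Weibull law used to seed the pitting
#' parameter lambda_p on the initial exposed surface of a coupon:
#' \deqn{f(x; \gamma, \psi) = \frac{\gamma}{\psi}
#'   \left(\frac{x}{\psi}\right)^{\gamma - 1}
#'   e^{-(x/\psi)^\gamma}, \quad x \ge 0,}
#' and 0 for negative `x`.  `gamma` is the shape and `psi` the scale;
#' both are dimensionless.
#'
#' @param x numeric vector of quantiles.
#' @param gamma shape parameter, > 0.
#' @param psi scale parameter, > 0.
#' @return Numeric vector of densities, same length as `x`.
#' @seealso [weibull_interval_prob()], [sample_lambda()]
#' @export
#' @examples
#' weibull_pit_pdf(0, gamma = 1, psi = 1)   # exponential at the origin
#' weibull_pit_pdf(-1, gamma = 2, psi = 3)  # 0: no negative pit rates
weibull_pit_pdf <- function(x, gamma, psi) {
  check_shape_params(gamma, psi)
  out <- numeric(length(x))
  nn <- x >= 0
  z <- x[nn] / psi
  out[nn] <- (gamma / psi) * z^(gamma - 1) * exp(-z^gamma)
  # x = 0 with gamma < 1 diverges, with gamma = 1 the limit is 1/psi
  out[x == 0] <- if (gamma < 1) Inf else if (gamma == 1) 1 / psi else 0
  out
}

#' Probability that the pitting parameter falls in an interval
#'
#' Closed-form Weibull interval probability
#' \eqn{P(a \le \lambda_p \le b) = e^{-(\max(a,0)/\psi)^\gamma} -
#'      e^{-(\max(b,0)/\psi)^\gamma}}.
#'
#' @param a,b interval endpoints, `a <= b`.  `b` may be `Inf`.
#' @inheritParams weibull_pit_pdf
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' weibull_interval_prob(0, Inf, 2, 1)          # total probability: 1
#' weibull_interval_prob(1, 2, gamma = 2, psi = 1) # exp(-1) - exp(-4)
weibull_interval_prob <- function(a, b, gamma, psi) {
  check_shape_params(gamma, psi)
  if (any(a > b)) {
    stop("interval endpoints must satisfy a <= b", call. = FALSE)
  }
  sf <- function(x) exp(-(pmax(x, 0) / psi)^gamma)
  sf(a) - sf(b)
}

#' Sample pitting parameters from the Weibull pit-field law
#'
#' Draws i.i.d. lambda_p values by inverse-CDF sampling,
#' \eqn{\lambda = \psi(-\ln U)^{1/\gamma}} with `U ~ Uniform(0, 1)`.
#' Draws consume the R random-number stream, so a fixed
#' [set.seed()] makes the pit field reproducible.
#'
#' @param n number of draws, >= 0.
#' @inheritParams weibull_pit_pdf
#' @return Numeric vector of `n` non-negative draws.
#' @export
sample_lambda <- function(n, gamma, psi) {
  check_shape_params(gamma, psi)
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  psi * (-log(runif(n)))^(1 / gamma)
}

check_shape_params <- function(gamma, psi) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    stop("'gamma' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi) || psi <= 0) {
    stop("'psi' must be a single positive number", call. = FALSE)
  }
  invisible(TRUE)
}
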