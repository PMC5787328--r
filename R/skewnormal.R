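#' Skew-normal density (half-normal location-mixture form)
#'
#' Density of `X = lambda * |Z0| + eps` with `Z0 ~ N(0, 1)` and
#' `eps ~ N(0, sigma2)`:
#'
#'   f(x) = 2 phi(x; 0, sigma2 + lambda^2) *
#'          Phi(lambda * x / (sigma * sqrt(sigma2 + lambda^2)))
#'
#' `lambda = 0` recovers N(0, sigma2).  The mean is `lambda * sqrt(2/pi)`
#' and the variance `sigma2 + lambda^2 * (1 - 2/pi)`; the mode stays near
#' zero, which is what makes the form attractive as a regularising prior
#' with a directional shift.
#'
#' @param x quantiles.
#' @param lambda asymmetry parameter (any real).
#' @param sigma2 scale variance, `> 0`.
#' @param log return log-density?
#' @return Density values.
#' @export
dskewnorm <- function(x, lambda, sigma2, log = FALSE) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("sigma2 must be a positive scalar")
  omega2 <- sigma2 + lambda^2
  ld <- log(2) + stats::dnorm(x, 0, sqrt(omega2), log = TRUE) +
    stats::pnorm(lambda * x / sqrt(sigma2 * omega2), log.p = TRUE)
  if (log) ld else exp(ld)
}

#' Sample from the skew-normal via its stochastic representation
#'
#' Draws `lambda * |z0| + sqrt(sigma2) * z1` with independent standard
#' normals, the same representation the Gibbs sampler exploits through one
#' half-normal auxiliary variable per SNP.
#'
#' @param n number of draws.
#' @param lambda asymmetry parameter.
#' @param sigma2 scale variance, `> 0`.
#' @return Numeric vector of `n` draws.
#' @export
rskewnorm <- function(n, lambda, sigma2) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("sigma2 must be a positive scalar")
  if (n < 1) stop("n must be >= 1")
  lambda * abs(stats::rnorm(n)) + sqrt(sigma2) * stats::rnorm(n)
}

#' Moments of the skew-normal in this parameterisation
#'
#' Helper for comparing the asymmetry parameter across parameterisations:
#' returns mean, variance, and the full variance `sigma2 + lambda^2 (1-2/pi)`
#' alongside the scale parameter.
#'
#' @inheritParams dskewnorm
#' @return Named list with `mean`, `var`, `sigma2_scale`.
#' @export
skewnorm_moments <- function(lambda, sigma2) {
  list(mean = lambda * sqrt(2 / pi),
       var = sigma2 + lambda^2 * (1 - 2 / pi),
       sigma2_scale = sigma2)
}

#' Sample from a normal truncated to the non-negative half line
#'
#' Inverse-CDF sampling through the upper tail, which remains accurate even
#' when `mean` is many standard deviations below zero (the tail probability
#' is carried in log-free form by `pnorm(..., lower.tail = FALSE)` and
#' inverted by `qnorm(..., lower.tail = FALSE)`).
#'
#' @param n number of draws.
#' @param mean,var mean and variance of the untruncated normal; `var > 0`.
#' @return `n` draws, all `>= 0`.
#' @export
rtruncnorm_nonneg <- function(n, mean, var) {
  if (!is.numeric(var) || any(var <= 0)) stop("var must be > 0")
  sd <- sqrt(var)
  a <- -mean / sd  # standardised lower bound
  q <- stats::pnorm(a, lower.tail = FALSE)  # mass above the bound
  z <- stats::qnorm(stats::runif(n) * q, lower.tail = FALSE)
  mean + sd * z
}
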