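# Full-conditional algebra of the Gibbs sweep, written out as plain
# functions.  The compiled kernel implements the same expressions with
# incremental residual bookkeeping; these are the reference forms used in
# documentation and unit tests, and for building custom samplers on top of
# the package.

#' Full conditional of a location effect
#'
#' For an effect with design column `w`, residual-adjusted data
#' `w'y* = wty` (with the effect's own contribution added back) and prior
#' precision `prior_prec` (0 for flat-prior effects such as the general
#' mean, `b` and parity effects; `1/sigma2` for Gaussian-prior effects):
#' the conditional is `N(mean, var)` with
#' `var = sigma2_e / (w'w + sigma2_e * prior_prec)` and
#' `mean = wty / (w'w + sigma2_e * prior_prec)`.
#'
#' @param wtw cross-product `w'w` over records.
#' @param wty adjusted right-hand side `w'(e + w beta_old)`.
#' @param sigma2_e residual variance.
#' @param prior_prec prior precision (0 = flat).
#' @return List with `mean` and `var`.
#' @export
cond_location <- function(wtw, wty, sigma2_e, prior_prec = 0) {
  denom <- wtw + sigma2_e * prior_prec
  if (denom <= 0) stop("undefined conditional: w'w = 0 under a flat prior")
  list(mean = wty / denom, var = sigma2_e / denom)
}

#' Full conditional of a dominance SNP effect
#'
#' `N(m, v)` with `v = 1 / (k'k/sigma2_e + 1/sigma2_d)` and
#' `m = v (k'y*/sigma2_e + lambda u / sigma2_d)`; with `lambda u = 0` this
#' is the ordinary ridge conditional.
#'
#' @param ktk cross-product of the dominance design column.
#' @param kty adjusted right-hand side.
#' @param sigma2_e,sigma2_d residual and dominance-scale variances.
#' @param lambda_u product of the asymmetry parameter and the SNP's
#'   auxiliary variable (the conditional prior mean of the effect).
#' @return List with `mean` and `var`.
#' @export
cond_dominance <- function(ktk, kty, sigma2_e, sigma2_d, lambda_u = 0) {
  v <- 1 / (ktk / sigma2_e + 1 / sigma2_d)
  list(mean = v * (kty / sigma2_e + lambda_u / sigma2_d), var = v)
}

#' Full conditional of a half-normal auxiliary variable
#'
#' `N(m, v)` truncated to `[0, Inf)` with `v = 1 / (1 + lambda^2/sigma2_d)`
#' and `m = v lambda d / sigma2_d`.  At `lambda = 0` this is the standard
#' half-normal `|N(0, 1)|`.
#'
#' @param lambda asymmetry parameter.
#' @param sigma2_d dominance-scale variance.
#' @param d_j current dominance effect of the SNP.
#' @return List with `mean`, `var` (of the untruncated normal).
#' @export
cond_auxiliary <- function(lambda, sigma2_d, d_j) {
  v <- 1 / (1 + lambda^2 / sigma2_d)
  list(mean = v * lambda * d_j / sigma2_d, var = v)
}

#' Full conditional of the asymmetry parameter
#'
#' With a flat prior, `lambda | u, d ~ N(sum(u d)/sum(u^2),
#' sigma2_d/sum(u^2))`.
#'
#' @param u auxiliary variables (non-negative).
#' @param d dominance effects.
#' @param sigma2_d dominance-scale variance.
#' @return List with `mean` and `var`.
#' @export
cond_lambda <- function(u, d, sigma2_d) {
  su2 <- sum(u^2)
  if (su2 <= 0) stop("degenerate conditional: sum(u^2) = 0")
  list(mean = sum(u * d) / su2, var = sigma2_d / su2)
}

#' Draw a variance from its scaled inverse chi-square full conditional
#'
#' Returns `(sum_sq + nu * S2) / chisq(n_terms + nu)` draws.  The long-run
#' mean is `(sum_sq + nu S2) / (n_terms + nu - 2)`.
#'
#' @param n number of draws.
#' @param sum_sq sum of squared effects (or residuals).
#' @param n_terms number of effects contributing to `sum_sq`.
#' @param nu,S2 prior degrees of freedom and scale.
#' @return Numeric vector of `n` variance draws.
#' @export
rvar_scaled_inv_chisq <- function(n, sum_sq, n_terms, nu, S2) {
  if (sum_sq < 0) stop("sum_sq must be >= 0")
  if (n_terms + nu <= 0) stop("improper posterior: n_terms + nu <= 0")
  (sum_sq + nu * S2) / stats::rchisq(n, df = n_terms + nu)
}
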