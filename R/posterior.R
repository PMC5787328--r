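#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(prob * n)` of the sorted samples;
#' ties in width are broken by the first (lowest) window.
#'
#' @param samples numeric vector of at least 100 draws.
#' @param prob target coverage (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 100) stop("hpd_interval needs at least 100 samples, got ", n)
  x <- sort(samples)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)  # which.min takes the first minimum
  c(x[i], x[i + m - 1L])
}

#' Posterior sign probability
#'
#' Fraction of draws strictly above (direction `"pos"`) or below
#' (direction `"neg"`) zero.
#'
#' @param samples numeric vector of draws.
#' @param direction `"pos"` or `"neg"`.
#' @return A fraction in `[0, 1]`.
#' @export
sign_probability <- function(samples, direction = c("pos", "neg")) {
  direction <- match.arg(direction)
  if (!length(samples)) stop("empty sample vector")
  if (direction == "pos") mean(samples > 0) else mean(samples < 0)
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated by the
#' initial-positive-sequence rule (consecutive lag pairs are summed while
#' their sum stays positive).  The estimate is capped at `n`; a constant
#' chain returns 0 with a warning.
#'
#' @param samples numeric vector of at least 100 draws.
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(samples) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 100) stop("effective_sample_size needs at least 100 samples")
  if (stats::sd(samples) == 0) {
    warning("constant chain: effective sample size is 0")
    return(0)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- as.numeric(stats::acf(samples, lag.max = lag_max,
                               plot = FALSE, demean = TRUE)$acf)
  # rho[1] is lag 0 = 1; pair sums Gamma_k = rho_{2k} + rho_{2k+1}
  tau <- 1
  k <- 2L
  while (k + 1L <= length(rho)) {
    gam <- rho[k] + rho[k + 1L]
    if (gam <= 0) break
    tau <- tau + 2 * gam
    k <- k + 2L
  }
  min(n, n / tau)
}

#' Geweke convergence z-score
#'
#' Compares the means of the first `first` and last `last` fractions of the
#' chain, standardised by spectral-density-at-zero variance estimates from
#' an autoregressive fit in each window.  Values beyond about |z| = 3 signal
#' mean drift.
#'
#' @param samples numeric vector of at least 1000 draws.
#' @param first,last window fractions (defaults 0.1 and 0.5).
#' @return The z-score (scalar).
#' @export
geweke_z <- function(samples, first = 0.1, last = 0.5) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 1000) stop("geweke_z needs at least 1000 samples, got ", n)
  if (first + last > 1) stop("window fractions overlap")
  w1 <- samples[seq_len(floor(first * n))]
  w2 <- samples[(n - floor(last * n) + 1L):n]
  if (stats::sd(w1) == 0 || stats::sd(w2) == 0)
    stop("zero variance within a window (constant chain?)")
  s1 <- .spectrum0_ar(w1)
  s2 <- .spectrum0_ar(w2)
  (mean(w1) - mean(w2)) / sqrt(s1 / length(w1) + s2 / length(w2))
}

# spectral density at frequency zero via an AR fit (order chosen by AIC)
.spectrum0_ar <- function(x) {
  fit <- stats::ar(x, aic = TRUE, order.max = min(20L, length(x) - 1L))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Posterior summary table for one parameter vector
#'
#' @param samples numeric vector of pooled draws.
#' @param name parameter label.
#' @return One-row data frame with mean, SD, HPD95 bounds, `P(>0)`, ESS and
#'   Geweke z (the last is `NA` for chains shorter than 1000).
#' @export
summarize_draws <- function(samples, name = "parameter") {
  z <- if (length(samples) >= 1000 && stats::sd(samples) > 0)
    tryCatch(geweke_z(samples), error = function(e) NA_real_) else NA_real_
  hpd <- if (length(samples) >= 100) hpd_interval(samples) else
    c(NA_real_, NA_real_)
  data.frame(parameter = name,
             mean = mean(samples), sd = stats::sd(samples),
             hpd95_low = hpd[1L], hpd95_high = hpd[2L],
             p_gt0 = sign_probability(samples, "pos"),
             ess = if (length(samples) >= 100 && stats::sd(samples) > 0)
               effective_sample_size(samples) else NA_real_,
             geweke_z = z,
             row.names = NULL)
}
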