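#' Per-record log-likelihood draws
#'
#' Gaussian record likelihood conditional on all location effects and the
#' residual variance: entry `(s, i)` is
#' `log N(y_i; fitted_i^(s), sigma2_e^(s))` computed from the fitted values
#' stored at each retained draw.
#'
#' @param fit a [dirdom_fit()] run with `store_fitted = TRUE`.
#' @return Matrix, draws in rows and records in columns.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "dirdom_fit"))
  if (is.null(fit$fitted_draws))
    stop("fit was run with store_fitted = FALSE")
  s2 <- fit$draws$sigma2_e
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("corrupt chain: non-positive residual variance draw")
  resid2 <- sweep(fit$fitted_draws, 1L, fit$y, function(f, y) (y - f)^2)
  L <- t(-0.5 * (log(2 * pi) + log(rep(s2, each = nrow(resid2))) +
                   sweep(resid2, 2L, s2, "/")))
  if (any(!is.finite(L))) stop("non-finite log-likelihood entries")
  L
}

#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance, `pD = Dbar - D(posterior mean)`
#' the effective number of parameters, and `DIC = Dbar + pD`.  The plug-in
#' deviance uses the posterior means of the per-record fitted values
#' (equivalent, by linearity, to plugging in posterior-mean location
#' effects) and of the residual variance.
#'
#' @param L log-likelihood matrix from [pointwise_loglik()].
#' @param loglik_at_posterior_mean total log-likelihood at the posterior
#'   mean; if `fit` is supplied it is computed from the fit.
#' @param fit optional [dirdom_fit()] used to compute the plug-in term.
#' @return List with `DIC`, `pD`, `Dbar`.
#' @export
dic <- function(L, loglik_at_posterior_mean = NULL, fit = NULL) {
  if (is.null(loglik_at_posterior_mean)) {
    if (is.null(fit)) stop("supply loglik_at_posterior_mean or fit")
    fbar <- rowMeans(fit$fitted_draws)
    s2bar <- mean(fit$draws$sigma2_e)
    loglik_at_posterior_mean <-
      sum(stats::dnorm(fit$y, fbar, sqrt(s2bar), log = TRUE))
  }
  Dbar <- mean(-2 * rowSums(L))
  pD <- Dbar - (-2 * loglik_at_posterior_mean)
  if (pD < 0)
    warning("negative pD (", signif(pD, 4),
            "): posterior may be far from Gaussian")
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Logarithm of the conditional predictive ordinate
#'
#' `CPO_i` is the harmonic mean of record `i`'s likelihood over the draws,
#' a leave-one-out predictive density estimate; `LogCPO = sum_i log CPO_i`
#' (higher is better).  Computed in log space with the log-sum-exp trick.
#' The harmonic-mean estimator is noisy, so the result carries the largest
#' single-draw contribution per record as a stability diagnostic.
#'
#' @param L log-likelihood matrix from [pointwise_loglik()].
#' @return List with `LogCPO`, per-record `log_cpo_i`, and
#'   `max_weight`: the largest share any single draw contributes to a
#'   record's harmonic mean.
#' @export
log_cpo <- function(L) {
  S <- nrow(L)
  negL <- -L
  mx <- apply(negL, 2L, max)
  lse <- mx + log(colSums(exp(sweep(negL, 2L, mx, "-"))))
  log_cpo_i <- log(S) - lse
  if (any(!is.finite(log_cpo_i)))
    stop("non-finite CPO for record(s) ",
         paste(head(which(!is.finite(log_cpo_i)), 5), collapse = ", "))
  max_weight <- max(exp(mx - lse))
  list(LogCPO = sum(log_cpo_i), log_cpo_i = log_cpo_i,
       max_weight = max_weight)
}

#' Compare fitted models by DIC and LogCPO
#'
#' Refuses to compare fits whose data fingerprints differ (different record
#' vectors or SNP sets).
#'
#' @param ... two or more named [dirdom_fit()] objects, or a single list of
#'   them.
#' @return Data frame with one row per model: `model`, `LogCPO`, `DIC`,
#'   `pD`, ranked by LogCPO (best first).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "dirdom_fit"))
    fits <- fits[[1L]]
  if (length(fits) < 2L) stop("need at least two fits to compare")
  stopifnot(all(vapply(fits, inherits, logical(1), "dirdom_fit")))
  fps <- lapply(fits, `[[`, "data_fingerprint")
  if (!all(vapply(fps, function(f) isTRUE(all.equal(f, fps[[1L]])),
                  logical(1))))
    stop("fits were made on different datasets; refusing to compare")
  rows <- lapply(fits, function(f) {
    L <- pointwise_loglik(f)
    di <- dic(L, fit = f)
    cp <- log_cpo(L)
    data.frame(model = f$model, LogCPO = cp$LogCPO, DIC = di$DIC,
               pD = di$pD)
  })
  out <- do.call(rbind, rows)
  out[order(-out$LogCPO), , drop = FALSE]
}
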