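#' @export
print.dirdom_fit <- function(x, ...) {
  cat("Directional-dominance genomic model (", x$model, ")\n", sep = "")
  cat("  records:", length(x$y), " animals:", length(x$ind_ids),
      " SNPs:", length(x$freqs), "\n")
  ctl <- x$control
  cat(sprintf("  chains: %d x %d iterations (burn-in %d, thin %d), %d draws kept\n",
              ctl$n_chains, ctl$n_iter, ctl$burn_in, ctl$thin, nrow(x$draws)))
  cat(sprintf("  worst incremental-residual drift: %.2e\n", x$max_resid_diff))
  co <- coef(x)
  cat("  posterior means:\n")
  print(round(co, 5))
  invisible(x)
}

#' @export
coef.dirdom_fit <- function(object, ...) {
  d <- object$draws
  keep <- c("mu", if (object$include_b) "b", "t2", "t3", "t4",
            if (object$include_lambda) "lambda",
            "sigma2_r", "sigma2_c", "sigma2_a", "sigma2_d", "sigma2_e")
  vapply(keep, function(p) mean(d[[p]]), numeric(1))
}

#' Posterior summary of a directional-dominance fit
#'
#' One row per reported quantity, mirroring the usual variance-component
#' table for this model family: `b`, the five variances, `lambda`, and the
#' derived `I_D`, `V_A`, `V_D`, `h2`, `d2`.  Rows for parameters the model
#' excludes are kept but filled with `NA` so tables align across models.
#'
#' @param object a [dirdom_fit()].
#' @param ... unused.
#' @return A `summary.dirdom_fit` object: data frame of summary rows plus
#'   attributes with the model label.
#' @export
summary.dirdom_fit <- function(object, ...) {
  d <- object$draws
  dd <- object$derived
  rows <- list()
  add <- function(samples, name) {
    rows[[length(rows) + 1L]] <<- summarize_draws(samples, name)
  }
  na_row <- function(name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = name, mean = NA_real_, sd = NA_real_, hpd95_low = NA_real_,
      hpd95_high = NA_real_, p_gt0 = NA_real_, ess = NA_real_,
      geweke_z = NA_real_, row.names = NULL)
  }
  if (object$include_b) add(d$b, "b") else na_row("b")
  add(d$sigma2_a, "sigma2_a")
  add(d$sigma2_d, "sigma2_d")
  add(d$sigma2_r, "sigma2_r")
  add(d$sigma2_c, "sigma2_c")
  if (object$include_lambda) add(d$lambda, "lambda") else na_row("lambda")
  add(d$sigma2_e, "sigma2_e")
  add(dd$I_D, "I_D")
  add(dd$V_A, "V_A")
  add(dd$V_D, "V_D")
  add(dd$h2, "h2")
  add(dd$d2, "d2")
  out <- do.call(rbind, rows)
  attr(out, "model") <- object$model
  class(out) <- c("summary.dirdom_fit", "data.frame")
  out
}

#' @export
print.summary.dirdom_fit <- function(x, digits = 4, ...) {
  cat("Posterior summary (model ", attr(x, "model"), ")\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a summary in "mean (SD)" format
#'
#' @param s a `summary.dirdom_fit`.
#' @param path optional TSV output path.
#' @return Data frame with columns `parameter` and `estimate`.
#' @export
format_summary_table <- function(s, path = NULL) {
  stopifnot(inherits(s, "summary.dirdom_fit"))
  est <- ifelse(is.na(s$mean), "-",
                sprintf("%.4g (%.4g)", s$mean, s$sd))
  out <- data.frame(parameter = s$parameter, estimate = est)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' @export
fitted.dirdom_fit <- function(object, ...) {
  if (is.null(object$fitted_draws))
    stop("fit was run with store_fitted = FALSE")
  rowMeans(object$fitted_draws)
}

#' @export
residuals.dirdom_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' Genomic predictions for (new) genotypes
#'
#' Breeding values and dominance deviations from the posterior-mean SNP
#' effects, encoded against the training allele frequencies.
#'
#' @param object a [dirdom_fit()].
#' @param geno a [geno_matrix()] with the same SNPs as the training data;
#'   defaults to predicting for the training animals is not possible because
#'   the fit does not retain the genotypes, so `geno` is required.
#' @param ... unused.
#' @return Data frame with `id`, `s_a` (breeding value) and `s_d`
#'   (dominance deviation).
#' @export
predict.dirdom_fit <- function(object, geno, ...) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(geno$freqs) != length(object$freqs))
    stop("genotype matrix does not match the training SNP set")
  eff <- snp_effects(object)
  G <- geno
  G$freqs <- object$freqs  # encode against training frequencies
  Z <- encode_design(G, "freq")$Z
  W <- dominance_deviation_codes(G$counts, object$freqs)
  data.frame(id = G$ind_ids,
             s_a = as.numeric(Z %*% eff$alpha),
             s_d = as.numeric(W %*% eff$d),
             row.names = NULL)
}

#' Posterior-predictive simulation of phenotype records
#'
#' Draws new record vectors from randomly chosen retained posterior draws:
#' the stored fitted values plus Gaussian residual noise at that draw's
#' residual variance.
#'
#' @param object a [dirdom_fit()] run with `store_fitted = TRUE`.
#' @param nsim number of replicate record vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return Data frame with `nsim` columns of simulated records.
#' @export
simulate.dirdom_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted_draws))
    stop("fit was run with store_fitted = FALSE")
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(object$fitted_draws)
  n <- length(object$y)
  picks <- sample.int(S, nsim, replace = TRUE)
  out <- vapply(picks, function(s) {
    object$fitted_draws[, s] +
      stats::rnorm(n, 0, sqrt(object$draws$sigma2_e[s]))
  }, numeric(n))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Trace plots for the key scalar parameters
#'
#' @param x a [dirdom_fit()].
#' @param pars parameters to plot; defaults to the active ones.
#' @param ... passed to [plot()].
#' @export
plot.dirdom_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars))
    pars <- c("mu", if (x$include_b) "b", if (x$include_lambda) "lambda",
              "sigma2_a", "sigma2_d", "sigma2_e")
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), 2),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    v <- x$draws[[p]]
    graphics::plot(v, type = "l", xlab = "kept draw", ylab = p, main = p, ...)
    graphics::abline(h = mean(v), col = 2)
  }
  invisible(x)
}

#' Export per-animal genetic values of a fit
#'
#' Posterior means and SDs of breeding values and dominance deviations for
#' the training animals, computed from the retained SNP-effect draws and the
#' training genotypes.
#'
#' @param fit a [dirdom_fit()].
#' @param geno the training [geno_matrix()].
#' @param path optional TSV output path.
#' @return Data frame `id, s_a_mean, s_a_sd, s_d_mean, s_d_sd`.
#' @export
genomic_value_table <- function(fit, geno, path = NULL) {
  stopifnot(inherits(fit, "dirdom_fit"), inherits(geno, "geno_matrix"))
  p <- fit$freqs
  Z <- encode_design(geno, "freq")$Z
  W <- dominance_deviation_codes(geno$counts, p)
  qp <- 1 - 2 * p
  # alpha draws: a + (q - p) d, draws x snp
  alpha_draws <- fit$a_draws + sweep(fit$d_draws, 2L, qp, "*")
  sa <- Z %*% t(alpha_draws)        # animals x draws
  sd_ <- W %*% t(fit$d_draws)
  out <- data.frame(id = geno$ind_ids,
                    s_a_mean = rowMeans(sa),
                    s_a_sd = apply(sa, 1L, stats::sd),
                    s_d_mean = rowMeans(sd_),
                    s_d_sd = apply(sd_, 1L, stats::sd),
                    row.names = NULL)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
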