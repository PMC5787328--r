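#' MCMC control settings
#'
#' Defaults follow a five-chain protocol scaled to desk-size data; each chain
#' draws its own sub-seed from `seed` so chains are independent and the whole
#' run is reproducible.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations per chain (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of independent chains.
#' @param seed integer seed for the whole run.
#' @param check_every recompute the residual vector from scratch every this
#'   many iterations and record the worst discrepancy (0 disables).
#' @param use_parity,use_group,use_perm include the parity, contemporary
#'   group and permanent-environment terms.  Disabling them is intended for
#'   validation against closed-form posteriors on toy data.
#' @param fixed_variances `NULL`, or a named list
#'   (`sigma2_r`, `sigma2_c`, `sigma2_a`, `sigma2_d`, `sigma2_e`) that
#'   freezes all variances at the given values (validation mode).
#' @param fixed_u freeze the half-normal auxiliary variables at their
#'   initial value `sqrt(2/pi)` (validation mode).
#' @param translation_move include the joint shift update of the
#'   dominance-effect mean with compensating changes in `b` and `mu`.  The
#'   move leaves the posterior unchanged and removes the slow random walk
#'   along the near-collinear direction between the dominance mean and the
#'   homozygosity regression; disabling it is intended only for validating
#'   the plain single-site sampler against it.
#' @param store_fitted keep the per-record fitted value at every retained
#'   draw (needed for DIC / LogCPO).
#' @return A list of class `dirdom_control`.
#' @export
dirdom_control <- function(n_iter = 7500, burn_in = 2500, thin = 5,
                           n_chains = 5, seed = 1, check_every = 1000,
                           use_parity = TRUE, use_group = TRUE,
                           use_perm = TRUE, fixed_variances = NULL,
                           fixed_u = FALSE, translation_move = TRUE,
                           store_fitted = TRUE) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (thin < 1 || n_chains < 1) stop("thin and n_chains must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), check_every = as.integer(check_every),
                 use_parity = use_parity, use_group = use_group,
                 use_perm = use_perm, fixed_variances = fixed_variances,
                 fixed_u = fixed_u, translation_move = translation_move,
                 store_fitted = store_fitted),
            class = "dirdom_control")
}

#' Hyperprior settings for the variance components
#'
#' Every variance carries a scaled inverse chi-square prior `nu * S2 /
#' chisq_nu`.  The scales are resolved at fit time from an ANOVA-style
#' partition of the phenotypic variance: shares of `var(y)` assigned to the
#' additive, dominance, contemporary-group, permanent-environment and
#' residual components.  SNP-level scales divide the genetic shares by the
#' number of SNPs times the mean of `2pq` (additive) or of `(2pq)^2`
#' (dominance), so the implied genetic variances match the shares.
#'
#' @param nu prior degrees of freedom (one value for all components).
#' @param shares named numeric partition of the phenotypic variance; must
#'   sum to at most 1.
#' @return A list of class `dirdom_hyper`.
#' @export
dirdom_hyper <- function(nu = 4.2,
                         shares = c(add = 0.10, dom = 0.05, group = 0.05,
                                    perm = 0.10, resid = 0.70)) {
  need <- c("add", "dom", "group", "perm", "resid")
  if (!all(need %in% names(shares))) stop("shares must name ",
                                          paste(need, collapse = ", "))
  if (any(shares < 0) || sum(shares) > 1 + 1e-8)
    stop("shares must be non-negative and sum to at most 1")
  structure(list(nu = nu, shares = shares[need]), class = "dirdom_hyper")
}

.resolve_hyper <- function(hyper, vy, p, m) {
  twopq <- 2 * p * (1 - p)
  s <- hyper$shares
  S2 <- c(r = s[["group"]] * vy,
          c = s[["perm"]] * vy,
          a = s[["add"]] * vy / (m * mean(twopq)),
          d = s[["dom"]] * vy / (m * mean(twopq^2)),
          e = s[["resid"]] * vy)
  list(nu = rep(hyper$nu, 5), S2 = S2)
}

#' Fit a directional-dominance genomic model by Gibbs sampling
#'
#' Fits the repeated-record SNP model
#' `y = 1 mu + h b + X t + W r + Q c + Z a + K d + e` under one of four
#' nested specifications:
#'
#' * `"SN"`: symmetric dominance, no covariate (`b = 0`, `lambda = 0`);
#' * `"SC"`: symmetric dominance plus the regression `b` on average
#'   individual homozygosity (genomic inbreeding);
#' * `"AN"`: skew-Gaussian dominance with asymmetry `lambda`, no covariate;
#' * `"Full"`: both `b` and `lambda`.
#'
#' @param geno a QC'd [geno_matrix()].
#' @param pheno data frame with columns `id` (matching genotyped
#'   individuals), `parity` (integer, capped at 4 = "4th or later"),
#'   `group` (contemporary-group identifier, e.g. farm-year-month) and `y`
#'   (the trait record, e.g. litter size).
#' @param model one of `"SN"`, `"SC"`, `"AN"`, `"Full"`.
#' @param control a [dirdom_control()].
#' @param hyper a [dirdom_hyper()].
#' @param verbose print per-chain progress.
#' @return An object of class `dirdom_fit`; see [summary.dirdom_fit()].
#' @export
dirdom_fit <- function(geno, pheno, model = c("SN", "SC", "AN", "Full"),
                       control = dirdom_control(), hyper = dirdom_hyper(),
                       verbose = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(geno, "geno_matrix"), inherits(control, "dirdom_control"),
            inherits(hyper, "dirdom_hyper"))
  need <- c("id", "parity", "group", "y")
  if (!all(need %in% names(pheno)))
    stop("pheno must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(pheno$y))) stop("non-finite phenotype records")
  unknown <- setdiff(as.character(pheno$id), geno$ind_ids)
  if (length(unknown))
    stop("phenotype records for ungenotyped animals: ",
         paste(head(unknown, 5), collapse = ", "))

  include_b <- model %in% c("SC", "Full")
  include_lambda <- model %in% c("AN", "Full")

  animal <- match(as.character(pheno$id), geno$ind_ids) - 1L
  parity <- pmin(pmax(as.integer(pheno$parity), 1L), 4L) - 1L
  group <- as.integer(factor(pheno$group)) - 1L
  y <- as.numeric(pheno$y)
  des <- encode_design(geno, "freq")
  h <- homozygosity(geno)
  m <- ncol(des$Z)

  hp <- .resolve_hyper(hyper, stats::var(y), geno$freqs, m)
  fixed <- !is.null(control$fixed_variances)
  init_var <- if (fixed) {
    fv <- control$fixed_variances
    need_v <- c("sigma2_r", "sigma2_c", "sigma2_a", "sigma2_d", "sigma2_e")
    if (!all(need_v %in% names(fv)))
      stop("fixed_variances must name ", paste(need_v, collapse = ", "))
    as.numeric(fv[need_v])
  } else {
    as.numeric(hp$S2)
  }

  set.seed(control$seed)
  chain_seeds <- sample.int(.Machine$integer.max, control$n_chains)

  scal_names <- c("mu", "b", "lambda", "t2", "t3", "t4", "sigma2_r",
                  "sigma2_c", "sigma2_a", "sigma2_d", "sigma2_e")
  scal_list <- a_list <- d_list <- fit_list <- vector("list", control$n_chains)
  max_resid_diff <- 0
  t0 <- proc.time()[["elapsed"]]
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    res <- .gibbs_chain(y, animal, parity, group, des$Z, des$K, as.numeric(h),
                        include_b, include_lambda,
                        control$use_parity, control$use_group,
                        control$use_perm,
                        hp$nu, as.numeric(hp$S2), init_var, mean(y),
                        control$n_iter, control$burn_in, control$thin,
                        fixed, control$fixed_u, control$translation_move,
                        control$store_fitted, control$check_every)
    colnames(res$scalars) <- scal_names
    scal_list[[ch]] <- res$scalars
    a_list[[ch]] <- res$a
    d_list[[ch]] <- res$d
    if (control$store_fitted) fit_list[[ch]] <- res$fitted
    max_resid_diff <- max(max_resid_diff, res$max_resid_diff)
    if (verbose)
      message(sprintf("chain %d/%d: %d draws kept, worst residual drift %.2e",
                      ch, control$n_chains, res$n_keep, res$max_resid_diff))
  }

  draws <- as.data.frame(do.call(rbind, scal_list))
  n_keep <- nrow(scal_list[[1L]])
  draws$chain <- rep(seq_len(control$n_chains), each = n_keep)
  draws$iter <- rep(control$burn_in + control$thin * (seq_len(n_keep) - 1L) + 1L,
                    control$n_chains)

  out <- structure(list(
    model = model,
    include_b = include_b, include_lambda = include_lambda,
    draws = draws,
    a_draws = do.call(rbind, a_list),
    d_draws = do.call(rbind, d_list),
    fitted_draws = if (control$store_fitted) do.call(cbind, fit_list),
    y = y, animal_id = as.character(pheno$id),
    ind_ids = geno$ind_ids, freqs = geno$freqs, snp_ids = geno$snp_ids,
    h = h,
    control = control, hyper = hp,
    data_fingerprint = .data_fingerprint(y, geno),
    max_resid_diff = max_resid_diff,
    elapsed = proc.time()[["elapsed"]] - t0), class = "dirdom_fit")
  out$derived <- derived_draws(out)
  out
}

.data_fingerprint <- function(y, geno) {
  c(n_rec = length(y), sum_y = sum(y), ss_y = sum(y^2),
    n_ind = length(geno$ind_ids), n_snp = length(geno$freqs),
    sum_p = sum(geno$freqs))
}

#' Posterior means of the SNP effects of a fit
#'
#' @param fit a `dirdom_fit`.
#' @return List with vectors `a`, `d`, `alpha`.
#' @export
snp_effects <- function(fit) {
  stopifnot(inherits(fit, "dirdom_fit"))
  a <- colMeans(fit$a_draws)
  d <- colMeans(fit$d_draws)
  list(a = a, d = d, alpha = substitution_effects(a, d, fit$freqs))
}
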