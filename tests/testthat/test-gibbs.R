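test_that("full-conditional algebra matches hand-computed cases", {
  # sample-mean conditional: flat prior, w = ones, n = 100, mean(y*) = 3
  cc <- cond_location(wtw = 100, wty = 300, sigma2_e = 1, prior_prec = 0)
  expect_equal(cc$mean, 3)
  expect_equal(cc$var, 1 / 100)
  # infinite prior precision forces the coefficient to zero
  cc2 <- cond_location(100, 300, 1, prior_prec = 1e12)
  expect_lt(abs(cc2$mean), 1e-6)
  expect_error(cond_location(0, 0, 1, 0), "flat prior")
  # ridge estimate on 4 records, single SNP: w'y*/(w'w + s2e/s2a)
  w <- c(1, -1, 0, 2); ystar <- c(0.5, -0.2, 0.3, 1.1)
  s2e <- 1.5; s2a <- 0.3
  cc3 <- cond_location(sum(w^2), sum(w * ystar), s2e, 1 / s2a)
  expect_equal(cc3$mean, sum(w * ystar) / (sum(w^2) + s2e / s2a))

  # dominance conditional: k'k = 1, s2e = s2d = 1, lambda*u = 1, k'y* = 3
  cd <- cond_dominance(1, 3, 1, 1, lambda_u = 1)
  expect_equal(cd$mean, 2)
  expect_equal(cd$var, 0.5)
  # lambda = 0 reduces to the plain ridge conditional
  cd0 <- cond_dominance(1, 3, 1, 1, lambda_u = 0)
  cl0 <- cond_location(1, 3, 1, prior_prec = 1)
  expect_equal(cd0, cl0)
  # no-data case draws from the conditional prior N(lambda u, s2d)
  cdp <- cond_dominance(0, 0, 1, 0.7, lambda_u = 0.4)
  expect_equal(cdp$mean, 0.4)
  expect_equal(cdp$var, 0.7)

  # auxiliary conditional examples
  ca <- cond_auxiliary(lambda = 1, sigma2_d = 1, d_j = 2)
  expect_equal(ca$mean, 1)
  expect_equal(ca$var, 0.5)
  ca2 <- cond_auxiliary(3, 1, 0)
  expect_equal(ca2$mean, 0)
  expect_equal(ca2$var, 0.1)
  ca0 <- cond_auxiliary(0, 1, 5)
  expect_equal(ca0, list(mean = 0, var = 1))  # half-normal at lambda = 0

  # lambda conditional
  cl <- cond_lambda(u = c(1, 1), d = c(2, 2), sigma2_d = 1)
  expect_equal(cl$mean, 2)
  expect_equal(cl$var, 0.5)
  expect_equal(cond_lambda(c(1, 2), c(0, 0), 1)$mean, 0)
  expect_error(cond_lambda(c(0, 0), c(1, 1), 1), "degenerate")
})

test_that("scaled inverse chi-square draws have the stated long-run mean", {
  set.seed(61)
  # nu -> 0 limit with huge n_terms concentrates at sum_sq / n_terms
  x <- rvar_scaled_inv_chisq(200, sum_sq = 2e6, n_terms = 1e6, nu = 0, S2 = 1)
  expect_lt(max(abs(x - 2)), 0.05)
  # long-run mean (sum_sq + nu S2)/(n + nu - 2)
  y <- rvar_scaled_inv_chisq(2e5, 50, 20, 4, 2)
  expect_lt(abs(mean(y) - 58 / 22) / (58 / 22), 0.02)
  # prior-only draw
  z <- rvar_scaled_inv_chisq(2e5, 0, 0, 4, 1)
  expect_lt(abs(mean(z) - 4 / 2) / 2, 0.05)
  expect_error(rvar_scaled_inv_chisq(1, -1, 10, 4, 1), "sum_sq")
  expect_error(rvar_scaled_inv_chisq(1, 1, 0, 0, 1), "improper")
})

test_that("identical seeds give bit-identical chains", {
  sim <- small_sim("Full", seed = 17, n_sows = 60, n_snp = 80, n_groups = 10)
  ctl <- quick_control(99, n_iter = 400, burn_in = 100)
  f1 <- dirdom_fit(sim$geno, sim$pheno, "Full", control = ctl)
  f2 <- dirdom_fit(sim$geno, sim$pheno, "Full", control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$a_draws, f2$a_draws)
  expect_identical(f1$d_draws, f2$d_draws)
  f3 <- dirdom_fit(sim$geno, sim$pheno, "Full",
                   control = quick_control(100, n_iter = 400, burn_in = 100))
  expect_false(identical(f1$draws$mu, f3$draws$mu))
})

test_that("incrementally maintained residuals agree with recomputation", {
  sim <- small_sim("Full", seed = 18, n_sows = 80, n_snp = 150, n_groups = 12)
  fit <- dirdom_fit(sim$geno, sim$pheno, "Full",
                    control = quick_control(3, n_iter = 2500, burn_in = 500,
                                            check_every = 500))
  expect_lt(fit$max_resid_diff, 1e-8)
})

test_that("fixed-variance Gibbs matches the closed-form joint posterior", {
  # 8 records on 4 animals, 3 SNPs, lambda = 0, b absent, no nuisance terms:
  # the stationary distribution of (mu, a, d) is the exact Gaussian solved
  # from the mixed-model equations
  counts <- matrix(c(0, 1, 2, 1, 1, 0, 2, 0, 1, 1, 2, 1), 4, 3, byrow = TRUE)
  g <- geno_matrix(counts, ind_ids = paste0("A", 1:4))
  ph <- data.frame(id = rep(paste0("A", 1:4), each = 2), parity = 1,
                   group = "g1",
                   y = c(10.2, 11.5, 12.1, 11.8, 9.9, 10.4, 12.5, 13.0))
  fv <- list(sigma2_r = 1, sigma2_c = 1, sigma2_a = 0.5, sigma2_d = 0.4,
             sigma2_e = 1.2)
  ctl <- dirdom_control(n_iter = 52000, burn_in = 2000, thin = 1,
                        n_chains = 1, seed = 5, use_parity = FALSE,
                        use_group = FALSE, use_perm = FALSE,
                        fixed_variances = fv, store_fitted = FALSE)
  fit <- dirdom_fit(g, ph, "SN", control = ctl)

  des <- encode_design(g, "freq")
  idx <- match(ph$id, g$ind_ids)
  W <- cbind(1, des$Z[idx, ], des$K[idx, ])
  P <- diag(c(0, rep(1 / fv$sigma2_a, 3), rep(1 / fv$sigma2_d, 3)))
  C <- crossprod(W) / fv$sigma2_e + P
  exact <- as.numeric(solve(C, crossprod(W, ph$y) / fv$sigma2_e))

  gibbs_mean <- c(mean(fit$draws$mu), colMeans(fit$a_draws),
                  colMeans(fit$d_draws))
  chains <- cbind(fit$draws$mu, fit$a_draws, fit$d_draws)
  mc_se <- apply(chains, 2, function(v)
    sd(v) / sqrt(effective_sample_size(v)))
  expect_true(all(abs(gibbs_mean - exact) < 3.5 * mc_se))
  # marginal posterior variances match the MME inverse diagonal
  exact_var <- diag(solve(C))
  expect_true(all(abs(apply(chains, 2, var) / exact_var - 1) < 0.15))
})

test_that("the sampler aborts cleanly on inconsistent inputs", {
  sim <- small_sim("SN", seed = 19, n_sows = 30, n_snp = 40, n_groups = 5)
  ph_bad <- sim$pheno
  ph_bad$id[1] <- "ghost"
  expect_error(dirdom_fit(sim$geno, ph_bad, "SN"), "ungenotyped")
  ph_nf <- sim$pheno
  ph_nf$y[3] <- NA
  expect_error(dirdom_fit(sim$geno, ph_nf, "SN"), "non-finite phenotype")
  expect_error(dirdom_control(n_iter = 100, burn_in = 100), "exceed")
})
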