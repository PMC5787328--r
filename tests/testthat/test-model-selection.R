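test_that("pointwise log-likelihood entries match direct evaluation", {
  sim <- small_sim("SN", seed = 23, n_sows = 40, n_snp = 50, n_groups = 8)
  fit <- dirdom_fit(sim$geno, sim$pheno, "SN",
                    control = quick_control(7, n_iter = 600, burn_in = 200))
  L <- pointwise_loglik(fit)
  expect_equal(dim(L), c(nrow(fit$draws), length(fit$y)))
  # plug-in checks
  s <- 5; i <- 3
  expect_equal(L[s, i],
               dnorm(fit$y[i], fit$fitted_draws[i, s],
                     sqrt(fit$draws$sigma2_e[s]), log = TRUE))
  # perfect fit at unit variance gives -log(2 pi)/2
  expect_equal(dnorm(0, 0, 1, log = TRUE), -0.5 * log(2 * pi))
  # residual 2 at variance 4
  expect_equal(dnorm(2, 0, 2, log = TRUE), -0.5 * log(8 * pi) - 0.5)
  # row sums equal an independent whole-vector computation
  s2 <- fit$draws$sigma2_e
  total_direct <- vapply(seq_len(nrow(L)), function(k)
    sum(dnorm(fit$y, fit$fitted_draws[, k], sqrt(s2[k]), log = TRUE)),
    numeric(1))
  expect_equal(rowSums(L), total_direct, tolerance = 1e-10)
})

test_that("DIC arithmetic and degenerate-chain behaviour", {
  # two-draw toy with hand-computed deviances 10 and 14, deviance at mean 11
  L <- rbind(-5, -7)  # one record; -2 loglik = 10, 14
  res <- dic(L, loglik_at_posterior_mean = -5.5)
  expect_equal(res$Dbar, 12)
  expect_equal(res$pD, 1)
  expect_equal(res$DIC, 13)
  # degenerate chain: all draws identical -> pD = 0, DIC = Dbar
  Ld <- matrix(-3, nrow = 50, ncol = 4)
  resd <- dic(Ld, loglik_at_posterior_mean = -12)
  expect_equal(resd$pD, 0)
  expect_equal(resd$DIC, resd$Dbar)
  # conjugate normal-mean model: pD approximates one effective parameter
  set.seed(71)
  n <- 40; y <- rnorm(n, 2, 1)
  post_mean <- mean(y) # flat prior, known variance 1
  mus <- rnorm(4000, post_mean, 1 / sqrt(n))
  Lc <- t(vapply(mus, function(m) dnorm(y, m, 1, log = TRUE), numeric(n)))
  resc <- dic(Lc, loglik_at_posterior_mean = sum(dnorm(y, post_mean, 1,
                                                       log = TRUE)))
  expect_lt(abs(resc$pD - 1), 0.15)
  expect_warning(dic(L, loglik_at_posterior_mean = -8), "negative pD")
})

test_that("LogCPO is the harmonic-mean predictive density, log-sum-exp safe", {
  # single draw: LogCPO = total log-likelihood of that draw
  L1 <- matrix(c(-1.2, -0.8, -2), 1)
  expect_equal(log_cpo(L1)$LogCPO, sum(L1))
  # two draws, likelihoods 0.5 and 0.25 -> CPO = 1/3
  L2 <- matrix(log(c(0.5, 0.25)), 2, 1)
  expect_equal(log_cpo(L2)$log_cpo_i, log(1 / 3))
  # extreme magnitudes do not overflow
  L3 <- matrix(c(-800, -900, -700), 3, 1)
  expect_true(is.finite(log_cpo(L3)$LogCPO))
  # thinning refinement leaves the criteria stable on a toy chain
  set.seed(72)
  n <- 30; y <- rnorm(n)
  mus <- rnorm(8000, mean(y), 1 / sqrt(n))
  Lfull <- t(vapply(mus, function(m) dnorm(y, m, 1, log = TRUE), numeric(n)))
  half <- Lfull[seq(1, 8000, by = 2), ]
  expect_lt(abs(log_cpo(Lfull)$LogCPO - log_cpo(half)$LogCPO), 0.05)
})

test_that("comparison refuses fits from different datasets", {
  simA <- small_sim("SN", seed = 25, n_sows = 40, n_snp = 50, n_groups = 8)
  simB <- small_sim("SN", seed = 26, n_sows = 40, n_snp = 50, n_groups = 8)
  ctl <- quick_control(11, n_iter = 400, burn_in = 100)
  fA <- dirdom_fit(simA$geno, simA$pheno, "SN", control = ctl)
  fA2 <- dirdom_fit(simA$geno, simA$pheno, "SC", control = ctl)
  fB <- dirdom_fit(simB$geno, simB$pheno, "SN", control = ctl)
  cmp <- compare_models(fA, fA2)
  expect_setequal(cmp$model, c("SN", "SC"))
  expect_error(compare_models(fA, fB), "different datasets")
  # a model compared with itself gives identical criteria
  cmp2 <- compare_models(fA, fA)
  expect_equal(cmp2$LogCPO[1], cmp2$LogCPO[2])
  expect_equal(cmp2$DIC[1], cmp2$DIC[2])
})
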