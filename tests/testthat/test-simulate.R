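test_that("scenario validation and presets encode the four truths", {
  expect_equal(sim_scenario("SN")$b_true, 0)
  expect_equal(sim_scenario("SN")$lambda_true, 0)
  expect_equal(sim_scenario("SC")$b_true, -12)
  expect_equal(sim_scenario("SC")$lambda_true, 0)
  expect_gt(sim_scenario("AN")$lambda_true, 0)
  sc <- sim_scenario("AN", b_true = -3)
  expect_equal(sc$b_true, -3)  # overrides win over presets
  expect_error(sim_scenario("SN", sigma2_e = -1), ">= 0")
  expect_error(sim_scenario("SN", missing_rate = 1), "missing_rate")
})

test_that("simulation is seed-reproducible and internally consistent", {
  sc <- sim_scenario("Full", n_sows = 60, n_snp = 100, n_groups = 10)
  s1 <- dirdom_simulate(sc, seed = 5)
  s2 <- dirdom_simulate(sc, seed = 5)
  expect_identical(s1$geno$counts, s2$geno$counts)
  expect_identical(s1$pheno$y, s2$pheno$y)
  s3 <- dirdom_simulate(sc, seed = 6)
  expect_false(identical(s1$pheno$y, s3$pheno$y))
  # every phenotyped animal is genotyped; parity runs 1..n within sow
  expect_true(all(s1$pheno$id %in% s1$geno$ind_ids))
  expect_true(all(s1$pheno$parity %in% 1:4))
  # realized truth quantities recompute from stored effects: same code path
  gv <- genetic_variances(s1$truth$a, s1$truth$d, s1$geno$freqs)
  expect_identical(gv$V_A, s1$truth$V_A)
  expect_identical(gv$V_D, s1$truth$V_D)
  expect_identical(inbreeding_depression(s1$truth$b, s1$truth$d,
                                         s1$geno$freqs), s1$truth$I_D)
  # infeasible design rejected
  expect_error(dirdom_simulate(sim_scenario("SN", n_sows = 3, n_snp = 10,
                                            n_groups = 500), seed = 1),
               "infeasible")
})

test_that("generator and sampler share one design-encoding implementation", {
  sim <- dirdom_simulate(sim_scenario("SN", n_sows = 30, n_snp = 40,
                                      n_groups = 6), seed = 8)
  des <- encode_design(sim$geno, "freq")
  g_manual <- as.numeric(des$Z %*% sim$truth$a + des$K %*% sim$truth$d)
  # reconstruct the genotypic part of y from the truth record
  idx <- match(sim$pheno$id, sim$geno$ind_ids)
  sc <- sim$truth$scenario
  rebuilt <- sim$truth$mu + sc$b_true * homozygosity(sim$geno)[idx] +
    sc$parity_effects[sim$pheno$parity] +
    sim$truth$group_effects[as.integer(sub("g", "", sim$pheno$group))] +
    sim$truth$perm_effects[idx] + g_manual[idx]
  resid <- sim$pheno$y - rebuilt
  expect_equal(sd(resid), sqrt(sc$sigma2_e), tolerance = 0.2)
  expect_lt(abs(mean(resid)), 0.5)
})

test_that("default desk scenario lands on the target phenotype scale", {
  means <- sds <- numeric(5)
  for (s in 1:5) {
    sim <- dirdom_simulate(sim_scenario("Full"), seed = 100 + s)
    means[s] <- mean(sim$pheno$y)
    sds[s] <- sd(sim$pheno$y)
  }
  expect_true(all(abs(means - 11.7) < 0.2))
  expect_true(all(sds > 2.4 & sds < 3.4))
})

test_that("written datasets round-trip and carry a checksummed manifest", {
  dir <- tempfile("ds")
  sim <- dirdom_simulate(sim_scenario("SC", n_sows = 25, n_snp = 30,
                                      n_groups = 5), seed = 4)
  paths <- write_dataset(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_genotypes(paths[["geno"]], "tsv")
  expect_equal(back$counts, sim$geno$counts)
  man <- readLines(paths[["manifest"]])
  expect_true(any(grepl("^seed: 4$", man)))
  expect_true(any(grepl("^md5_geno: [0-9a-f]{32}$", man)))
  # same seed twice -> identical checksums
  dir2 <- tempfile("ds")
  paths2 <- write_dataset(dirdom_simulate(sim_scenario(
    "SC", n_sows = 25, n_snp = 30, n_groups = 5), seed = 4), dir2)
  expect_identical(unname(tools::md5sum(paths[["geno"]])),
                   unname(tools::md5sum(paths2[["geno"]])))
  unlink(c(dir, dir2), recursive = TRUE)
})
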