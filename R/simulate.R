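#' Simulation scenario for a sow litter-size recording scheme
#'
#' Defines the generative conditions the models assume: SNP-wise genotypes
#' with per-individual inbreeding, Gaussian additive SNP effects,
#' skew-Gaussian dominance SNP effects, a regression of the phenotype on
#' realized average homozygosity, parity and contemporary-group structure,
#' permanent-environment effects and Gaussian residuals.
#'
#' The `truth` presets mirror the four model specifications: `"Full"` puts
#' directional dominance in both channels (`b_true = -6`,
#' `lambda_true = 0.012`), `"SC"` only in the homozygosity regression
#' (`b_true = -12`), `"AN"` only in the skewness (`lambda_true = 0.012`),
#' and `"SN"` in neither.  Defaults are scaled so a default-size dataset has
#' phenotypic mean near `mean_litter` and SD near 2.9 piglets, with genetic
#' variances of the magnitude seen in commercial pig litter-size analyses.
#'
#' @param truth one of `"Full"`, `"SC"`, `"AN"`, `"SN"`.
#' @param n_sows number of genotyped sows.
#' @param n_snp number of SNPs.
#' @param n_groups number of contemporary (farm-year-month) groups.
#' @param parity_probs probability that a sow has 1, 2, 3 or 4 litters.
#' @param maf_range allele frequencies are uniform on this interval.
#' @param inbreeding_beta shape parameters of the Beta distribution of
#'   per-sow inbreeding coefficients (drives between-sow homozygosity
#'   variation, as pedigree inbreeding does in a closed nucleus line).
#' @param missing_rate fraction of genotype calls set missing.
#' @param mean_litter target population mean litter size.
#' @param b_true,lambda_true directional-dominance truth (override presets).
#' @param sigma2_a,sigma2_d per-SNP additive/dominance effect variances.
#' @param sigma2_r,sigma2_c,sigma2_e group, permanent-environment and
#'   residual variances.
#' @param parity_effects fixed parity effects (first parity is reference 0).
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(truth = c("Full", "SC", "AN", "SN"),
                         n_sows = 500, n_snp = 2000, n_groups = 100,
                         parity_probs = c(0.1, 0.2, 0.3, 0.4),
                         maf_range = c(0.05, 0.95),
                         inbreeding_beta = c(2, 18),
                         missing_rate = 0,
                         mean_litter = 11.7,
                         b_true = NULL, lambda_true = NULL,
                         sigma2_a = 9.3e-4, sigma2_d = 1.9e-3,
                         sigma2_r = 0.16, sigma2_c = 0.48, sigma2_e = 6.6,
                         parity_effects = c(0, 0.3, 0.5, 0.4)) {
  truth <- match.arg(truth)
  preset <- switch(truth,
                   Full = c(b = -6, lambda = 0.012),
                   SC = c(b = -12, lambda = 0),
                   AN = c(b = 0, lambda = 0.012),
                   SN = c(b = 0, lambda = 0))
  if (is.null(b_true)) b_true <- preset[["b"]]
  if (is.null(lambda_true)) lambda_true <- preset[["lambda"]]
  if (any(c(sigma2_a, sigma2_d, sigma2_r, sigma2_c, sigma2_e) < 0))
    stop("variances must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  sc <- list(truth = truth, n_sows = n_sows, n_snp = n_snp,
             n_groups = n_groups, parity_probs = parity_probs,
             maf_range = maf_range, inbreeding_beta = inbreeding_beta,
             missing_rate = missing_rate, mean_litter = mean_litter,
             b_true = b_true, lambda_true = lambda_true,
             sigma2_a = sigma2_a, sigma2_d = sigma2_d, sigma2_r = sigma2_r,
             sigma2_c = sigma2_c, sigma2_e = sigma2_e,
             parity_effects = parity_effects)
  class(sc) <- "sim_scenario"
  sc
}

# genotype counts with per-individual inbreeding F_i: with probability F_i
# the two alleles are identical by descent (homozygote at frequency p),
# otherwise Hardy-Weinberg
.sim_genotypes <- function(n_ind, p, Fi) {
  m <- length(p)
  counts <- matrix(0L, n_ind, m)
  for (i in seq_len(n_ind)) {
    ibd <- stats::runif(m) < Fi[i]
    hw <- stats::rbinom(m, 2L, p)
    hom <- 2L * (stats::runif(m) < p)
    counts[i, ] <- ifelse(ibd, hom, hw)
  }
  counts
}

#' Simulate a genotype/phenotype dataset with known truth
#'
#' Draws genotypes, SNP effects and phenotype records under the scenario and
#' returns them with a truth record.  Genotype design codes used to build
#' the genotypic values go through [encode_design()] — the same code path
#' the sampler uses — and realized `V_A`, `V_D` and `I_D` are computed with
#' [genetic_variances()] and [inbreeding_depression()] on the realized
#' allele frequencies.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return List with `geno` (a [geno_matrix()]), `pheno` (data frame
#'   `id, parity, group, y`) and `truth` (scenario, per-SNP effects,
#'   per-animal values and realized summary quantities).
#' @export
dirdom_simulate <- function(scenario = sim_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(seed)

  p0 <- stats::runif(sc$n_snp, sc$maf_range[1L], sc$maf_range[2L])
  Fi <- stats::rbeta(sc$n_sows, sc$inbreeding_beta[1L], sc$inbreeding_beta[2L])
  counts <- .sim_genotypes(sc$n_sows, p0, Fi)
  ids <- sprintf("sow%04d", seq_len(sc$n_sows))
  if (sc$missing_rate > 0) {
    miss <- stats::runif(length(counts)) < sc$missing_rate
    counts[miss] <- NA
  }
  geno <- geno_matrix(counts, ind_ids = ids,
                      snp_ids = sprintf("snp%05d", seq_len(sc$n_snp)))

  a_true <- stats::rnorm(sc$n_snp, 0, sqrt(sc$sigma2_a))
  d_true <- rskewnorm(sc$n_snp, sc$lambda_true, sc$sigma2_d)

  # records: each sow farrows in parities 1..n_par
  n_par <- sample.int(4L, sc$n_sows, replace = TRUE, prob = sc$parity_probs)
  rec_animal <- rep(seq_len(sc$n_sows), n_par)
  rec_parity <- unlist(lapply(n_par, seq_len), use.names = FALSE)
  n_rec <- length(rec_animal)
  if (sc$n_groups > n_rec)
    stop("infeasible design: more contemporary groups (", sc$n_groups,
         ") than records (", n_rec, ")")
  rec_group <- sample.int(sc$n_groups, n_rec, replace = TRUE)

  des <- encode_design(geno, "freq")
  g_ind <- as.numeric(des$Z %*% a_true + des$K %*% d_true)
  h <- homozygosity(geno)
  r_true <- stats::rnorm(sc$n_groups, 0, sqrt(sc$sigma2_r))
  c_true <- stats::rnorm(sc$n_sows, 0, sqrt(sc$sigma2_c))
  e <- stats::rnorm(n_rec, 0, sqrt(sc$sigma2_e))

  systematic <- sc$b_true * h[rec_animal] + sc$parity_effects[rec_parity] +
    r_true[rec_group] + c_true[rec_animal] + g_ind[rec_animal]
  mu_used <- sc$mean_litter - mean(systematic)
  y <- mu_used + systematic + e

  gv <- genetic_variances(a_true, d_true, geno$freqs)
  vals <- genomic_values(geno, a_true, d_true)
  truth <- list(scenario = sc, seed = seed, mu = mu_used,
                b = sc$b_true, lambda = sc$lambda_true,
                a = a_true, d = d_true,
                s_a = vals$s_a, s_d = vals$s_d,
                V_A = gv$V_A, V_D = gv$V_D,
                I_D = inbreeding_depression(sc$b_true, d_true, geno$freqs),
                group_effects = r_true, perm_effects = c_true,
                inbreeding = Fi)
  list(geno = geno,
       pheno = data.frame(id = ids[rec_animal], parity = rec_parity,
                          group = sprintf("g%03d", rec_group), y = y),
       truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Genotypes go out in the TSV dialect of [write_genotypes()], phenotypes
#' and per-SNP truth as TSV, plus a key-value manifest with the seed and
#' file checksums.
#'
#' @param sim result of [dirdom_simulate()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(geno = file.path(dir, "genotypes.tsv"),
             pheno = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.txt"))
  write_genotypes(sim$geno, paths[["geno"]], "tsv")
  utils::write.table(sim$pheno, paths[["pheno"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- sim$truth
  utils::write.table(data.frame(snp_id = sim$geno$snp_ids, a = tr$a, d = tr$d),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sums <- tools::md5sum(paths[c("geno", "pheno", "truth")])
  names(sums) <- c("geno", "pheno", "truth")
  manifest <- c(paste0("seed: ", tr$seed),
                paste0("truth: ", tr$scenario$truth),
                paste0("mu: ", tr$mu),
                paste0("b_true: ", tr$b),
                paste0("lambda_true: ", tr$lambda),
                paste0("V_A: ", tr$V_A),
                paste0("V_D: ", tr$V_D),
                paste0("I_D: ", tr$I_D),
                paste0("md5_", names(sums), ": ", sums))
  writeLines(manifest, paths[["manifest"]])
  invisible(paths)
}

# Plant deterministic QC violations into a genotype matrix:
# - n_low_maf SNP columns rewritten to a single heterozygote (MAF = 1/(2n))
# - n_low_call individuals given missing calls on `miss_per_ind` SNPs chosen
#   outside the low-MAF set and spread so no SNP loses more than one call
.plant_qc_violations <- function(geno, n_low_maf = 0, n_low_call = 0,
                                 miss_per_ind = NULL) {
  counts <- geno$counts
  n <- nrow(counts); m <- ncol(counts)
  low_maf <- seq_len(n_low_maf)
  for (j in low_maf) {
    counts[, j] <- 0L
    counts[1L + (j %% n), j] <- 1L
  }
  if (n_low_call > 0) {
    if (is.null(miss_per_ind))
      miss_per_ind <- ceiling(0.051 * m)  # call rate just below 0.95
    bad_ind <- n - seq_len(n_low_call) + 1L
    snp_pool <- setdiff(seq_len(m), low_maf)
    for (k in seq_along(bad_ind)) {
      take <- snp_pool[seq.int((k - 1L) * miss_per_ind + 1L,
                               k * miss_per_ind)]
      counts[bad_ind[k], take] <- NA
    }
  }
  geno_matrix(counts, ind_ids = geno$ind_ids, snp_ids = geno$snp_ids)
}

#' Build a seeded test fixture
#'
#' `"tiny"` is a 20-sow, 50-SNP dataset with planted QC violations: exactly
#' 5 SNPs with minor allele frequency below 0.05 and 2 individuals with
#' call rate below 0.95 (their missing calls are spread so no SNP's call
#' rate drops below 0.95).  `"desk"` is the default scenario.  Files are
#' written with [write_dataset()]; the manifest carries md5 checksums.
#'
#' @param size `"tiny"` or `"desk"`.
#' @param dir output directory.
#' @param seed integer seed.
#' @return Named vector of file paths, invisibly (as [write_dataset()]).
#' @export
make_fixture <- function(size = c("tiny", "desk"), dir = tempfile("fixture"),
                         seed = 1) {
  size <- match.arg(size)
  if (size == "desk") {
    sim <- dirdom_simulate(sim_scenario(), seed = seed)
    return(write_dataset(sim, dir))
  }
  sc <- sim_scenario("SN", n_sows = 20, n_snp = 50, n_groups = 5,
                     maf_range = c(0.25, 0.75))
  sim <- dirdom_simulate(sc, seed = seed)
  # re-draw columns whose realized MAF drifted near the threshold so the
  # planted violations are the only ones
  counts <- sim$geno$counts
  maf <- pmin(sim$geno$freqs, 1 - sim$geno$freqs)
  for (j in which(maf < 0.15)) {
    repeat {
      cj <- stats::rbinom(nrow(counts), 2L, 0.5)
      f <- sum(cj) / (2 * length(cj))
      if (min(f, 1 - f) >= 0.15) break
    }
    counts[, j] <- cj
  }
  geno <- geno_matrix(counts, sim$geno$ind_ids, sim$geno$snp_ids)
  sim$geno <- .plant_qc_violations(geno, n_low_maf = 5, n_low_call = 2,
                                   miss_per_ind = 3)
  write_dataset(sim, dir)
}
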