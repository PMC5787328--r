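# Shared small fixtures, built in code.

# tiny genotype matrix with known frequencies
tiny_geno <- function() {
  counts <- rbind(c(0, 1, 2, 2, 1),
                  c(1, 1, 1, 1, 1),
                  c(2, 1, 0, 2, 0),
                  c(1, 0, 1, 1, 2))
  geno_matrix(counts, ind_ids = paste0("A", 1:4))
}

# small simulated dataset shared by several sampler tests; per-SNP effect
# variances are scaled up so total V_A / V_D stay at desk-scenario magnitude
# despite the reduced SNP panel
small_sim <- function(truth = "AN", seed = 7, n_sows = 120, n_snp = 300,
                      n_groups = 25) {
  scale <- 2000 / n_snp
  dirdom_simulate(sim_scenario(truth, n_sows = n_sows, n_snp = n_snp,
                               n_groups = n_groups,
                               sigma2_a = 9.3e-4 * scale,
                               sigma2_d = 1.9e-3 * scale), seed = seed)
}

quick_control <- function(seed, n_iter = 1500, burn_in = 500, ...) {
  dirdom_control(n_iter = n_iter, burn_in = burn_in, thin = 2, n_chains = 1,
                 seed = seed, ...)
}
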