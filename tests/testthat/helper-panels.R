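# shared fixture builders; everything is generated in code at test time

make_panel <- function(n = 100, p = 300, K = 1, divergence = 0,
                       h2 = 0.5, n_qtl = "polygenic", n_years = 3,
                       seed = 42, ld_block_size = 10,
                       admixture_concentration = 0.5) {
  cfg <- sim_config(n_accessions = n, n_markers = p, n_subpops = K,
                    divergence = divergence, ld_block_size = ld_block_size,
                    admixture_concentration = admixture_concentration,
                    seed = seed)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim$geno, n_qtl = n_qtl, h2 = h2,
                            n_years = n_years, seed = seed + 1)
  list(cfg = cfg, G = sim$geno, q = sim$q_matrix_true,
       records = ph$records, truth = ph$truth)
}

# full-data mixed-model BLUPs, the usual reference for predictive ability
panel_blups <- function(panel) {
  fit_pheno_mixed_model(panel$records)$blups
}

# direct phenotypic target: noiseless y = Zc u (+ optional noise), skipping
# the mixed model when the test does not need it
tbv_target <- function(panel) panel$truth$true_breeding_values
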