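#!/usr/bin/env Rscript
# Build the synthetic study: a structured inbred panel with GBS-like call
# defects plus three years of phenotypes for three traits, and write the
# raw artifacts (VCF, phenotype CSV, truth sidecar).

source("analysis/helpers.R")

study <- get_study()
cfg <- study$cfg
say("panel: %d accessions x %d markers, %d subpopulations",
    cfg$n_accessions, cfg$n_markers, cfg$n_subpops)

deg <- degrade_genotypes(study$sim$geno, cfg,
                         n_multiallelic_decoys = 25L,
                         n_low_maf_decoys = 40L)
vcf_path <- file.path(scratch_dir, "panel_raw.vcf")
write_vcf(deg$calls, vcf_path)
saveRDS(deg$bookkeeping, file.path(scratch_dir, "defect_bookkeeping.rds"))
say("wrote %s (%d sites incl. %d decoys)", vcf_path,
    nrow(deg$calls$site_meta), 65L)

pheno_path <- file.path(scratch_dir, "phenotypes.csv")
write_pheno_csv(study$records, pheno_path)
say("wrote %s (%d records over %d traits x 3 years)", pheno_path,
    nrow(study$records), length(trait_specs))

truth_summary <- data.frame(
  trait = names(study$truths),
  true_h2_entry_mean = vapply(study$truths, `[[`, 0, "true_h2"),
  sigma2_G = vapply(study$truths, function(t) t$true_sigma2[["G"]], 0),
  sigma2_GE = vapply(study$truths, function(t) t$true_sigma2[["GE"]], 0),
  sigma2_e = vapply(study$truths, function(t) t$true_sigma2[["e"]], 0),
  n_qtl = vapply(study$truths, function(t) length(t$qtl_indices), 0L))
write.table(truth_summary, file.path(res_dir, "01_truth_summary.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(q_matrix_true = study$sim$q_matrix_true,
       defect_counts = as.list(table(deg$bookkeeping$defect))),
  file.path(scratch_dir, "truth_sidecar.json"))
say("truth summary -> results/01_truth_summary.tsv")
print(truth_summary, row.names = FALSE)
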