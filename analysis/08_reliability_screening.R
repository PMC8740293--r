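#!/usr/bin/env Rscript
# Germplasm screening: mask 244 accessions as nonphenotyped, predict their
# GEBVs with RR-BLUP through the extended mixed-model equations, attach
# reliabilities, flag the top/bottom 50, and compare the predicted
# distribution with the observed BLUPs.

source("analysis/helpers.R")

study <- get_study()
G <- get_clean_geno()
blups <- get_blups()
tr <- "seed_yield"
y <- blups[[tr]]

set.seed(panel_seed + 9)
masked <- sample(names(y), 244)
observed <- setdiff(names(y), masked)
# refit the phenotypic model on the observed subset only (the screening
# situation: the masked accessions have no phenotype records at all)
obs_blups <- fit_pheno_mixed_model(
  study$records[study$records$trait_name == tr &
                  study$records$accession_id %in% observed, ])$blups

res <- suppressWarnings(predict_unphenotyped(G, obs_blups,
                                             model_tag = "RRBLUP"))
tab <- rank_and_flag(res$table, group_size = 50)
np <- tab[!tab$phenotyped, ]
say("%d nonphenotyped accessions: mean reliability %.3f (range %.3f-%.3f)",
    nrow(np), mean(np$reliability), min(np$reliability),
    max(np$reliability))

tbv <- study$truths[[tr]]$true_breeding_values[np$accession_id]
say("GEBV-TBV correlation among masked accessions: %.3f (r2 = %.3f)",
    cor(np$gebv, tbv), cor(np$gebv, tbv)^2)

cmp <- compare_distributions(unname(obs_blups), np$gebv)
say("observed BLUP range [%.1f, %.1f] vs predicted GEBV range [%.1f, %.1f]",
    cmp$range_observed[1], cmp$range_observed[2],
    cmp$range_predicted[1], cmp$range_predicted[2])
say("predicted GEBVs stay inside the observed range: %s (mean-diff p = %.2f)",
    cmp$predicted_within_observed_range, cmp$mean_diff_p_value)

top <- np[np$rank_group == "top50", ]
say("top-50 screening candidates: mean GEBV %.2f, mean reliability %.3f",
    mean(top$gebv), mean(top$reliability))

write.table(tab[order(-tab$gebv), ],
            file.path(res_dir, "08_screening_table.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(trait = tr, n_masked = nrow(np),
       mean_reliability_masked = mean(np$reliability),
       gebv_tbv_r2_masked = cor(np$gebv, tbv)^2,
       predicted_within_observed_range =
         cmp$predicted_within_observed_range,
       mean_diff_p_value = cmp$mean_diff_p_value),
  file.path(res_dir, "08_screening_summary.json"), auto_unbox = TRUE,
  digits = NA)
say("screening table -> results/08_screening_table.tsv")
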