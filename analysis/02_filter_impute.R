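#!/usr/bin/env Rscript
# Ingest the raw VCF, apply the site filters (biallelic, MAF >= 5%,
# QUAL >= 20, <= 80% missing, het < 20%), recode to {-1, 0, 1}, and impute
# residual missing calls by 5-nearest-neighbour genotype matching.

source("analysis/helpers.R")

raw <- read_vcf(file.path(scratch_dir, "panel_raw.vcf"))
say("ingested %d sites x %d accessions", nrow(raw$site_meta),
    length(raw$accession_ids))

flt <- apply_site_filters(raw)
print(flt$report)
book <- readRDS(file.path(scratch_dir, "defect_bookkeeping.rds"))
expected <- table(book$expected_filter, useNA = "no")
say("injected defect sites accounted for: %s",
    paste(names(expected), expected, sep = "=", collapse = ", "))

G <- encode_numeric(flt$calls)
say("numeric matrix: %.2f%% missing before imputation",
    100 * mean(is.na(G$values)))
G <- knn_impute(G, k = 5)
say("imputation complete: %d missing entries remain",
    sum(is.na(G$values)))

saveRDS(G, file.path(scratch_dir, "geno_clean.rds"))
rep <- flt$report
jsonlite::write_json(
  list(sites_in = rep$sites_in, removed = as.list(rep$removed),
       sites_out = rep$sites_out, params = rep$params),
  file.path(res_dir, "02_filter_report.json"), auto_unbox = TRUE)
say("clean genotypes cached; filter report -> results/02_filter_report.json")
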