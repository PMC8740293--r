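# Shared setup for the analysis drivers. Each numbered script can be run
# from the repository root with:  Rscript analysis/<script>.R
# Intermediate (large) artifacts go to scratch/, summary tables to results/.

suppressMessages(library(peagp))

res_dir <- "results"
scratch_dir <- "scratch/analysis"
dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(scratch_dir, showWarnings = FALSE, recursive = TRUE)

panel_seed <- 20160314L   # planting date of the first simulated season

# The emulated study panel: 480 inbred accessions, 5000 GBS markers in
# 7 admixed subpopulations, three traits spanning the observed
# heritability range, three years of single-plot records.
panel_config <- function() {
  sim_config(n_accessions = 480, n_markers = 5000, n_subpops = 7,
             admixture_concentration = 0.2, divergence = 0.25,
             ld_block_size = 25, maf_min = 0.05,
             missing_rate = 0.08, het_rate = 0.01, low_qual_rate = 0.02,
             seed = panel_seed)
}

trait_specs <- list(
  days_to_flower = list(h2 = 0.85, gxe = 0.10, n_qtl = 40),
  plant_height   = list(h2 = 0.75, gxe = 0.20, n_qtl = "polygenic"),
  seed_yield     = list(h2 = 0.45, gxe = 0.35, n_qtl = "polygenic"))

# build (or reload) the shared simulated study, cached under scratch/
get_study <- function() {
  cache <- file.path(scratch_dir, "study.rds")
  if (file.exists(cache)) return(readRDS(cache))
  cfg <- panel_config()
  sim <- simulate_genotypes(cfg)
  phs <- list()
  truths <- list()
  for (i in seq_along(trait_specs)) {
    tr <- names(trait_specs)[i]
    sp <- trait_specs[[i]]
    ph <- simulate_phenotypes(sim$geno, n_qtl = sp$n_qtl, h2 = sp$h2,
                              n_years = 3, gxe_fraction = sp$gxe,
                              seed = panel_seed + i, trait_name = tr)
    phs[[tr]] <- ph$records
    truths[[tr]] <- ph$truth
  }
  study <- list(cfg = cfg, sim = sim,
                records = do.call(rbind, phs), truths = truths)
  saveRDS(study, cache)
  study
}

# the filtered + imputed genotype matrix produced by 02_filter_impute.R
get_clean_geno <- function() {
  path <- file.path(scratch_dir, "geno_clean.rds")
  if (!file.exists(path)) {
    stop("run analysis/02_filter_impute.R first")
  }
  readRDS(path)
}

get_blups <- function() {
  path <- file.path(res_dir, "03_blups.tsv")
  if (!file.exists(path)) stop("run analysis/03_blup_heritability.R first")
  b <- utils::read.table(path, header = TRUE, sep = "\t")
  split(stats::setNames(b$blup, b$accession_id), b$trait)
}

say <- function(...) cat(sprintf(...), "\n")
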