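make_degraded <- function(n = 60, p = 46, seed = 9, ...) {
  cfg <- sim_config(n_accessions = n, n_markers = p, seed = seed)
  G <- simulate_genotypes(cfg)$geno
  list(G = G, deg = degrade_genotypes(G, cfg, ...))
}

test_that("clean panels pass every site filter", {
  d <- make_degraded()
  res <- apply_site_filters(d$deg$calls)
  expect_equal(res$report$sites_out, res$report$sites_in)
  expect_true(all(res$report$removed == 0))
})

test_that("constructed 50-site fixture loses exactly the injected defects", {
  d <- make_degraded(n = 60, p = 46, n_low_qual = 5, n_het_sites = 3,
                     n_low_maf_decoys = 4)
  expect_equal(nrow(d$deg$calls$site_meta), 50)
  res <- apply_site_filters(d$deg$calls)
  expect_equal(res$report$sites_out, 38)
  expect_equal(unname(res$report$removed["qual"]), 5)
  expect_equal(unname(res$report$removed["maf"]), 4)
  expect_equal(unname(res$report$removed["heterozygosity"]), 3)
  # survivors are exactly the sites the bookkeeping marks defect-free
  book <- d$deg$bookkeeping
  expect_setequal(res$calls$site_meta$site_id,
                  book$site_id[book$defect == "none"])
  # report conservation under the fixed rule order
  expect_equal(res$report$sites_in - sum(res$report$removed),
               res$report$sites_out)
})

test_that("designated high-missingness sites fall to the missingness rule", {
  d <- make_degraded(n = 50, p = 30, high_missing_sites = c(2, 7, 19))
  res <- apply_site_filters(d$deg$calls)
  expect_equal(unname(res$report$removed["missingness"]), 3)
  expect_false(any(c("M00002", "M00007", "M00019") %in%
                     res$calls$site_meta$site_id))
})

test_that("filter boundaries: MAF keep-at-0.05, QUAL keep-at-20, het strict", {
  n <- 100
  calls <- matrix(0L, n, 4)
  calls[1:5, 1] <- 2L    # MAF exactly 0.05 -> retained
  calls[1:4, 2] <- 2L    # MAF 0.04 -> removed
  calls[1:30, 3] <- 2L
  calls[1:20, 4] <- 1L   # het fraction exactly 0.20 -> removed (strict <)
  meta <- data.frame(site_id = paste0("S", 1:4), chrom = "1",
                     pos = 1:4 * 10L, ref = "A", alt = "G",
                     qual = c(30, 30, 19.9, 20.0), n_alt = 1L)
  # S1: MAF 0.05, QUAL 30 -> kept. S2: MAF 0.04 -> removed by MAF.
  # S3: QUAL 19.9 -> removed by QUAL. S4: QUAL 20.0 passes, het exactly
  # 0.20 -> removed by the strict het rule.
  res <- apply_site_filters(raw_call_set(meta, calls,
                                         sprintf("a%03d", 1:n)))
  expect_equal(res$calls$site_meta$site_id, "S1")
  expect_equal(unname(res$report$removed[c("maf", "qual",
                                           "heterozygosity")]),
               c(1L, 1L, 1L))
})

test_that("an all-missing site is removed by missingness, not an error", {
  calls <- cbind(rep(NA_integer_, 10), rep(c(0L, 2L), 5))
  meta <- data.frame(site_id = c("S1", "S2"), chrom = "1", pos = c(1L, 2L),
                     ref = "A", alt = "G", qual = 30, n_alt = 1L)
  res <- apply_site_filters(raw_call_set(meta, calls, paste0("a", 1:10)))
  expect_equal(res$calls$site_meta$site_id, "S2")
  expect_equal(unname(res$report$removed["missingness"]), 1)
})

test_that("filtering is idempotent", {
  d <- make_degraded(n = 40, p = 30, n_low_qual = 4, n_het_sites = 2,
                     n_low_maf_decoys = 2, n_multiallelic_decoys = 2)
  once <- apply_site_filters(d$deg$calls)
  twice <- apply_site_filters(once$calls)
  expect_identical(twice$calls$calls, once$calls$calls)
  expect_true(all(twice$report$removed == 0))
})

test_that("VCF write/read round-trips the call set", {
  d <- make_degraded(n = 25, p = 20, n_low_qual = 2, n_het_sites = 1,
                     n_low_maf_decoys = 1, n_multiallelic_decoys = 1)
  cfg2 <- sim_config(n_accessions = 25, n_markers = 20, missing_rate = 0.1,
                     seed = 99)
  G <- simulate_genotypes(cfg2)$geno
  deg <- degrade_genotypes(G, cfg2, n_low_qual = 2, n_het_sites = 2,
                           n_multiallelic_decoys = 1)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(deg$calls, path)
  back <- read_vcf(path)
  expect_identical(unname(back$calls), unname(deg$calls$calls))
  expect_equal(back$site_meta$pos, deg$calls$site_meta$pos)
  expect_equal(back$site_meta$qual, round(deg$calls$site_meta$qual, 2),
               tolerance = 1e-9)
  expect_equal(back$site_meta$n_alt, deg$calls$site_meta$n_alt)
  expect_identical(back$accession_ids, deg$calls$accession_ids)
})

test_that("triallelic sites are ingested with the alt list intact", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
               "1\t100\tv1\tA\tG\t50\t.\t.\tGT\t0/0\t0/1\t1/1",
               "1\t200\tv2\tA\tG,T\t50\t.\t.\tGT\t0/0\t1/2\t2/2"), path)
  rcs <- read_vcf(path)
  expect_equal(rcs$site_meta$n_alt, c(1L, 2L))
  expect_equal(unname(rcs$calls[, 2]), c(0L, 4L, 3L))
})

test_that("numeric encoding follows the major-allele convention", {
  # ref:alt copies 60:40 -> ref is major: hom-ref -> 1, het -> 0, hom-alt -> -1
  calls <- cbind(c(rep(0L, 25), rep(1L, 10), rep(2L, 15)))
  meta <- data.frame(site_id = "S1", chrom = "1", pos = 1L, ref = "A",
                     alt = "G", qual = 30, n_alt = 1L)
  G <- encode_numeric(raw_call_set(meta, calls, paste0("a", 1:50)))
  expect_equal(unname(G$values[, 1]),
               c(rep(1, 25), rep(0, 10), rep(-1, 15)))
  expect_equal(G$marker_meta$major, "A")
  expect_equal(G$marker_meta$maf, 0.4)

  # exactly 50/50 -> reference treated as major (documented tie-break)
  calls2 <- cbind(c(rep(0L, 10), rep(2L, 10)))
  meta2 <- meta; meta2$site_id <- "S2"
  G2 <- encode_numeric(raw_call_set(meta2, calls2, paste0("a", 1:20)))
  expect_equal(G2$marker_meta$major, "A")
  expect_equal(unname(G2$values[1, 1]), 1)

  # flipping ref/alt labels flips the column signs only
  calls3 <- 2L - calls
  meta3 <- meta; meta3$ref <- "G"; meta3$alt <- "A"
  G3 <- encode_numeric(raw_call_set(meta3, calls3, paste0("a", 1:50)))
  expect_equal(unname(G3$values[, 1]), unname(G$values[, 1]))
})

test_that("encoding preserves per-site MAF and missingness", {
  d <- make_degraded(n = 40, p = 25, seed = 17)
  cfg <- sim_config(n_accessions = 40, n_markers = 25, missing_rate = 0.15,
                    het_rate = 0.1, seed = 17)
  G0 <- simulate_genotypes(cfg)$geno
  deg <- degrade_genotypes(G0, cfg)
  res <- apply_site_filters(deg$calls)
  G <- encode_numeric(res$calls)
  cm <- res$calls$calls
  nonmiss <- colSums(!is.na(cm))
  f_alt <- colSums(cm, na.rm = TRUE) / (2 * nonmiss)
  expect_equal(G$marker_meta$maf, unname(pmin(f_alt, 1 - f_alt)))
  expect_equal(colMeans(is.na(G$values)), unname(colMeans(is.na(cm))),
               ignore_attr = TRUE)
})

test_that("knn imputation: identity, perfect neighbours, and accuracy", {
  panel <- make_panel(n = 30, p = 60, seed = 23)
  expect_identical(knn_impute(panel$G), panel$G)

  # an accession duplicated 6x with one masked call imputes to the shared value
  X <- panel$G$values
  dup <- X[rep(1, 6), ]
  rownames(dup) <- paste0("DUP", 1:6)
  Xd <- rbind(X[-1, ], dup)
  Xd["DUP1", 5] <- NA
  Gd <- genotype_matrix(Xd, panel$G$marker_meta)
  filled <- knn_impute(Gd, k = 5)
  expect_equal(filled$values["DUP1", 5], X[1, 5])

  # masked-entry recovery beats the major-genotype baseline
  set.seed(4)
  wins <- vapply(1:10, function(s) {
    p2 <- make_panel(n = 120, p = 200, K = 2, divergence = 0.3,
                     ld_block_size = 20, seed = 300 + s)
    X <- p2$G$values
    mask <- which(matrix(runif(length(X)) < 0.05, nrow(X)))
    Xm <- X; Xm[mask] <- NA
    imp <- knn_impute(genotype_matrix(Xm, p2$G$marker_meta), k = 5)
    acc <- mean(imp$values[mask] == X[mask])
    base <- mean(vapply(seq_len(ncol(X)), function(j) {
      maj <- ifelse(mean(X[, j] == 1) >= 0.5, 1, -1)
      mean((X[, j] == maj)[is.na(Xm[, j])])
    }, numeric(1)), na.rm = TRUE)
    acc > base
  }, logical(1))
  expect_true(all(wins))
})

test_that("imputation never alters observed entries and errors usefully", {
  panel <- make_panel(n = 25, p = 40, seed = 29)
  X <- panel$G$values
  X[1, 3] <- NA; X[5, 10] <- NA
  G <- genotype_matrix(X, panel$G$marker_meta)
  filled <- knn_impute(G, k = 3)
  obs <- !is.na(X)
  expect_identical(filled$values[obs], X[obs])
  expect_true(all(filled$values %in% c(-1, 0, 1)))

  X2 <- panel$G$values
  X2[, 7] <- NA
  expect_error(knn_impute(genotype_matrix(X2, panel$G$marker_meta)),
               "apply_site_filters")
})
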