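#' Raw genotype call set (VCF-level representation)
#'
#' Sites with per-accession genotype calls prior to filtering. Calls are
#' integer-coded: 0 = hom-ref, 1 = ref/alt1 het, 2 = hom-alt1,
#' 3 = hom-alt2, 4 = alt1/alt2 het (codes 3-4 occur only at multiallelic
#' sites), NA = missing.
#'
#' @param site_meta Data frame with columns site_id, chrom, pos, ref, alt
#'   (comma-separated for multiallelic sites), qual, n_alt.
#' @param calls Integer matrix, accessions x sites.
#' @param accession_ids Ordered accession identifiers (row order of `calls`).
#' @return An object of class `raw_call_set`.
#' @export
raw_call_set <- function(site_meta, calls, accession_ids = rownames(calls)) {
  stopifnot(nrow(site_meta) == ncol(calls),
            all(c("site_id", "chrom", "pos", "ref", "alt", "qual",
                  "n_alt") %in% names(site_meta)),
            all(site_meta$pos >= 1))
  rownames(calls) <- accession_ids
  colnames(calls) <- site_meta$site_id
  structure(list(site_meta = site_meta, calls = calls,
                 accession_ids = accession_ids),
            class = "raw_call_set")
}

#' @export
print.raw_call_set <- function(x, ...) {
  cat(sprintf("raw_call_set: %d accessions x %d sites (%d multiallelic)\n",
              length(x$accession_ids), nrow(x$site_meta),
              sum(x$site_meta$n_alt > 1)))
  invisible(x)
}

#' Inject GBS-like defects into a clean genotype panel
#'
#' Converts a complete inbred genotype matrix into a VCF-level call set with
#' controlled defects: a fraction of sites with QUAL below 20, a fraction
#' with artifactual heterozygous calls (25% of calls at the chosen sites, so
#' the per-site het fraction exceeds the 20% filter threshold), uniform
#' per-call missingness, optional designated high-missingness sites, and
#' appended decoy sites that are low-MAF or multiallelic. Ref/alt labels are
#' randomly swapped at ~30% of sites so numeric re-encoding must re-derive
#' the major allele. The returned bookkeeping lists which defect each site
#' carries and which filter rule is expected to remove it.
#'
#' @param G Complete [genotype_matrix()] (values in \{-1, 1\}).
#' @param cfg The [sim_config()] supplying the defect rates.
#' @param n_low_qual,n_het_sites Exact defect-site counts, overriding
#'   `cfg$low_qual_rate` / `cfg$het_rate` (defect sets are disjoint).
#' @param n_low_maf_decoys,n_multiallelic_decoys Counts of appended decoy
#'   sites (default from rates of 0).
#' @param high_missing_sites Optional indices of original sites whose calls
#'   are set missing at `high_missing_rate` (exceeding the 80% filter).
#' @param high_missing_rate Missingness rate for the designated sites.
#' @param seed Seed (default `cfg$seed + 1`).
#' @return A list with `calls` (a [raw_call_set()]) and `bookkeeping` (data
#'   frame: site_id, defect, expected_filter).
#' @export
degrade_genotypes <- function(G, cfg, n_low_qual = NULL, n_het_sites = NULL,
                              n_low_maf_decoys = 0L,
                              n_multiallelic_decoys = 0L,
                              high_missing_sites = NULL,
                              high_missing_rate = 0.9,
                              seed = cfg$seed + 1L) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  X <- G$values
  if (anyNA(X) || any(X == 0)) {
    stop("degrade_genotypes expects a complete homozygous panel")
  }
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  if (is.null(n_low_qual)) n_low_qual <- round(cfg$low_qual_rate * p)
  if (is.null(n_het_sites)) n_het_sites <- round(cfg$het_rate * p)
  if (n_low_qual + n_het_sites > p) stop("defect counts exceed site count")

  # per-site major allele and ref assignment (ref = major at ~70% of sites)
  ref_is_major <- stats::runif(p) < 0.7
  alleles <- c("A", "T", "G", "C")
  ref <- sample(alleles, p, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  # genotype +1 = hom-major: code 0 if ref is major, else code 2
  calls <- matrix(0L, n, p)
  calls[X == 1] <- ifelse(rep(ref_is_major, each = n)[X == 1], 0L, 2L)
  calls[X == -1] <- ifelse(rep(ref_is_major, each = n)[X == -1], 2L, 0L)

  defect <- rep("none", p)
  pool <- seq_len(p)
  if (!is.null(high_missing_sites)) {
    defect[high_missing_sites] <- "high_missing"
    pool <- setdiff(pool, high_missing_sites)
  }
  lq <- if (n_low_qual > 0) sample(pool, n_low_qual) else integer(0)
  pool <- setdiff(pool, lq)
  hs <- if (n_het_sites > 0) sample(pool, n_het_sites) else integer(0)
  defect[lq] <- "low_qual"
  defect[hs] <- "high_het"

  qual <- stats::runif(p, 25, 60)
  qual[lq] <- stats::runif(length(lq), 5, 19.5)

  for (j in hs) {
    k <- ceiling(0.25 * n)                    # het fraction >= 0.25 > 0.20
    calls[sample.int(n, k), j] <- 1L
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
    calls[miss] <- NA_integer_
  }
  for (j in high_missing_sites) {
    k <- round(high_missing_rate * n)
    calls[sample.int(n, k), j] <- NA_integer_
  }

  meta <- data.frame(site_id = colnames(X),
                     chrom = G$marker_meta$chrom,
                     pos = G$marker_meta$pos,
                     ref = ref, alt = alt, qual = qual, n_alt = 1L,
                     stringsAsFactors = FALSE)

  # appended decoy sites
  add_site <- function(id, chrom, pos, ref, alt, qual, n_alt, col, tag, rule) {
    meta <<- rbind(meta, data.frame(site_id = id, chrom = chrom, pos = pos,
                                    ref = ref, alt = alt, qual = qual,
                                    n_alt = n_alt, stringsAsFactors = FALSE))
    calls <<- cbind(calls, col)
    defect <<- c(defect, tag)
  }
  maxpos <- max(G$marker_meta$pos)
  if (n_low_maf_decoys > 0) {
    for (i in seq_len(n_low_maf_decoys)) {
      col <- rep(0L, n)
      nminor <- max(1L, floor(0.04 * n))      # MAF = nminor/n < 0.05
      col[sample.int(n, nminor)] <- 2L
      add_site(sprintf("DECOY_MAF_%02d", i), "1", maxpos + i * 100L,
               "A", "G", stats::runif(1, 25, 60), 1L, col, "low_maf", "maf")
    }
  }
  if (n_multiallelic_decoys > 0) {
    for (i in seq_len(n_multiallelic_decoys)) {
      col <- sample(c(0L, 2L, 3L), n, replace = TRUE,
                    prob = c(0.6, 0.25, 0.15))
      add_site(sprintf("DECOY_MULTI_%02d", i), "1",
               maxpos + (n_low_maf_decoys + i) * 100L,
               "A", "G,T", stats::runif(1, 25, 60), 2L, col,
               "multiallelic", "non_biallelic")
    }
  }

  expected_filter <- c(none = NA_character_, low_qual = "qual",
                       high_het = "heterozygosity",
                       high_missing = "missingness", low_maf = "maf",
                       multiallelic = "non_biallelic")[defect]
  book <- data.frame(site_id = meta$site_id, defect = defect,
                     expected_filter = unname(expected_filter),
                     stringsAsFactors = FALSE)
  list(calls = raw_call_set(meta, calls, rownames(X)), bookkeeping = book)
}

gt_strings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `3` = "2/2",
                `4` = "1/2")

#' Write a call set as a plain-text VCF v4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL columns and per-accession GT fields.
#'
#' @param calls A [raw_call_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  stopifnot(inherits(calls, "raw_call_set"))
  m <- calls$site_meta
  gt <- matrix(gt_strings[as.character(calls$calls)],
               nrow = nrow(calls$calls))
  gt[is.na(calls$calls)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", calls$accession_ids),
                    collapse = "\t"))
  body <- paste(m$chrom, m$pos, m$site_id, m$ref, m$alt,
                formatC(m$qual, format = "f", digits = 2), ".", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a raw call set
#'
#' Parses a VCF v4.2 (via vcfR) into the integer-coded call representation.
#' Multiallelic sites are retained (flagged through `n_alt`) so the
#' biallelic filter can remove them.
#'
#' @param path VCF file path.
#' @return A [raw_call_set()].
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  if (!"GT" %in% strsplit(v@gt[1, "FORMAT"], ":")[[1]]) {
    stop("VCF '", path, "' has no GT field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  code_of <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    a <- sort(as.integer(strsplit(s, "[/|]")[[1]]))
    if (anyNA(a)) return(NA_integer_)
    if (all(a == 0)) 0L
    else if (identical(a, c(0L, 1L))) 1L
    else if (all(a == 1)) 2L
    else if (all(a == 2)) 3L
    else if (identical(a, c(1L, 2L))) 4L
    else NA_integer_
  }
  codes <- vapply(unique(as.vector(gt)), code_of, integer(1))
  calls <- matrix(codes[as.vector(gt)], nrow = nrow(gt))
  calls <- t(calls)                           # accessions x sites
  ids <- fx[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fx[noid, "CHROM"], "_", fx[noid, "POS"])
  meta <- data.frame(site_id = ids, chrom = fx[, "CHROM"],
                     pos = as.integer(fx[, "POS"]), ref = fx[, "REF"],
                     alt = fx[, "ALT"],
                     qual = suppressWarnings(as.numeric(fx[, "QUAL"])),
                     n_alt = lengths(strsplit(fx[, "ALT"], ",")),
                     stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  raw_call_set(meta, calls, colnames(gt))
}
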