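site_stats <- function(calls) {
  # per-site stats on biallelic integer codes (0/1/2, NA missing)
  nonmiss <- colSums(!is.na(calls))
  altcopies <- colSums(calls * (calls <= 2), na.rm = TRUE)
  f_alt <- ifelse(nonmiss > 0, altcopies / (2 * nonmiss), NA_real_)
  maf <- pmin(f_alt, 1 - f_alt)
  miss <- colMeans(is.na(calls))
  het <- ifelse(nonmiss > 0, colSums(calls == 1, na.rm = TRUE) / nonmiss,
                NA_real_)
  list(maf = maf, miss = miss, het = het, f_alt = f_alt)
}

#' Apply the standard GBS site filters
#'
#' Retains sites that are biallelic, have minor allele frequency at or above
#' `maf_min` (computed on non-missing calls, counting 0/1/2 allele copies
#' per accession), QUAL at or above `qual_min`, missing-call fraction at or
#' below `max_missing`, and heterozygous-call fraction strictly below
#' `max_het`. Rules are applied in that fixed order and the report counts
#' removals per rule. A site whose calls are all missing has undefined MAF
#' and het fraction and is removed by the missingness rule.
#'
#' @param calls A [raw_call_set()].
#' @param maf_min Keep sites with MAF >= this (default 0.05).
#' @param qual_min Keep sites with QUAL >= this (default 20).
#' @param max_missing Keep sites with missing fraction <= this (default 0.80).
#' @param max_het Keep sites with het fraction < this (default 0.20, strict).
#' @return A list with `calls` (the filtered [raw_call_set()]) and `report`
#'   (class `filter_report`: sites_in, removed per rule, sites_out).
#' @export
apply_site_filters <- function(calls, maf_min = 0.05, qual_min = 20,
                               max_missing = 0.80, max_het = 0.20) {
  stopifnot(inherits(calls, "raw_call_set"), nrow(calls$site_meta) > 0)
  meta <- calls$site_meta
  cm <- calls$calls
  keep <- seq_len(nrow(meta))
  removed <- c(non_biallelic = 0L, maf = 0L, qual = 0L, missingness = 0L,
               heterozygosity = 0L)

  drop_rule <- function(keep, fail, rule) {
    removed[rule] <<- removed[rule] + sum(fail)
    keep[!fail]
  }
  keep <- drop_rule(keep, meta$n_alt[keep] != 1L, "non_biallelic")
  st <- site_stats(cm[, keep, drop = FALSE])
  keep <- drop_rule(keep, !is.na(st$maf) & st$maf < maf_min, "maf")
  keep <- drop_rule(keep, meta$qual[keep] < qual_min, "qual")
  st <- site_stats(cm[, keep, drop = FALSE])
  keep <- drop_rule(keep, st$miss > max_missing, "missingness")
  st <- site_stats(cm[, keep, drop = FALSE])
  keep <- drop_rule(keep, !is.na(st$het) & st$het >= max_het,
                    "heterozygosity")

  out <- raw_call_set(meta[keep, , drop = FALSE],
                      cm[, keep, drop = FALSE], calls$accession_ids)
  report <- structure(list(sites_in = nrow(meta), removed = removed,
                           sites_out = length(keep),
                           params = list(maf_min = maf_min,
                                         qual_min = qual_min,
                                         max_missing = max_missing,
                                         max_het = max_het),
                           note = paste("MAF rule keeps sites with MAF >=",
                                        "maf_min (removes MAF below 5% at",
                                        "defaults)")),
                      class = "filter_report")
  list(calls = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d sites in -> %d out\n", x$sites_in,
              x$sites_out))
  for (r in names(x$removed)) cat(sprintf("  removed by %s: %d\n", r,
                                          x$removed[[r]]))
  invisible(x)
}

#' Encode a biallelic call set as a numeric genotype matrix
#'
#' Codes each site as 1 = homozygous for the major allele (the more frequent
#' allele among non-missing calls; ties broken toward the reference allele),
#' -1 = homozygous minor, 0 = heterozygous; missing calls stay NA.
#'
#' @param calls A biallelic [raw_call_set()] (run [apply_site_filters()]
#'   first).
#' @return A [genotype_matrix()] with per-marker metadata (alleles, MAF,
#'   QUAL, missing and het rates).
#' @export
encode_numeric <- function(calls) {
  stopifnot(inherits(calls, "raw_call_set"))
  if (any(calls$site_meta$n_alt != 1L)) {
    stop("call set contains multiallelic sites; apply_site_filters first")
  }
  cm <- calls$calls
  st <- site_stats(cm)
  ref_major <- is.na(st$f_alt) | st$f_alt <= 0.5   # tie -> reference
  vals <- matrix(NA_real_, nrow(cm), ncol(cm))
  hom_ref <- !is.na(cm) & cm == 0L
  hom_alt <- !is.na(cm) & cm == 2L
  het <- !is.na(cm) & cm == 1L
  sgn <- rep(ifelse(ref_major, 1, -1), each = nrow(cm))
  vals[hom_ref] <- sgn[hom_ref]
  vals[hom_alt] <- -sgn[hom_alt]
  vals[het] <- 0
  dimnames(vals) <- list(calls$accession_ids, calls$site_meta$site_id)
  m <- calls$site_meta
  meta <- data.frame(marker_id = m$site_id, chrom = m$chrom, pos = m$pos,
                     major = ifelse(ref_major, m$ref, m$alt),
                     minor = ifelse(ref_major, m$alt, m$ref),
                     maf = st$maf, qual = m$qual, missing_rate = st$miss,
                     het_rate = st$het, stringsAsFactors = FALSE)
  genotype_matrix(vals, meta)
}

#' Impute missing genotypes by k-nearest neighbours
#'
#' Distances between accessions are mean squared genotype differences over
#' markers observed in both. Each missing entry takes the genotype most
#' supported by the k nearest accessions that observe that marker (nearer
#' neighbours are pulled in first; neighbours lacking the marker are
#' skipped). Vote ties resolve toward the more frequent observed genotype at
#' the marker, then toward 1. Observed entries are never altered.
#'
#' @param G A [genotype_matrix()] possibly containing NAs.
#' @param k Number of neighbours (default 5).
#' @return A complete [genotype_matrix()].
#' @export
knn_impute <- function(G, k = 5) {
  stopifnot(inherits(G, "genotype_matrix"), k >= 1)
  X <- G$values
  if (!anyNA(X)) return(G)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0)) {
    stop("marker(s) with zero observed calls: remove them with ",
         "apply_site_filters before imputing")
  }
  if (any(rowSums(obs) == 0)) {
    stop("accession(s) with zero observed markers")
  }
  X0 <- X; X0[!obs] <- 0
  M <- obs * 1
  S <- X0^2
  ss <- S %*% t(M)
  cnt <- M %*% t(M)
  D <- (ss + t(ss) - 2 * (X0 %*% t(X0))) / pmax(cnt, 1)
  D[cnt == 0] <- Inf
  diag(D) <- Inf
  ord <- apply(D, 1, order)                       # n x n, column i = order
  # per-marker frequency-ranked fallback genotype
  freq_pref <- apply(X, 2, function(col) {
    tb <- table(factor(col, levels = c(-1, 0, 1)))
    # order genotypes by frequency desc, then by value desc (prefers 1)
    as.numeric(names(sort(tb + c(0, 0.25, 0.5) / 4, decreasing = TRUE)))
  })
  filled <- knn_impute_cpp(X, obs, t(ord), as.integer(k), freq_pref)
  dimnames(filled) <- dimnames(X)
  G$values <- filled
  G$marker_meta$missing_rate_imputed <- 0
  genotype_matrix(filled, G$marker_meta)
}
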