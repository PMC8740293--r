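#' Simulation configuration for a structured inbred genotype panel
#'
#' Bundles the parameters of the synthetic genotype generator: an admixed
#' multi-subpopulation panel of fully inbred accessions with block-wise
#' linkage disequilibrium and GBS-like call defects.
#'
#' @param n_accessions Number of accessions (panel size).
#' @param n_markers Number of biallelic SNP markers.
#' @param n_subpops Number of ancestral subpopulations (K >= 1).
#' @param admixture_concentration Dirichlet concentration alpha for the
#'   per-accession ancestry proportions; small values give sharp membership,
#'   large values give heavy admixture.
#' @param divergence Allele-frequency divergence among subpopulations
#'   (Balding-Nichols F, in `[0, 1)`); 0 means no structure.
#' @param ld_block_size Number of consecutive markers sharing a latent
#'   haplotype signal; correlation decays with within-block distance.
#' @param maf_min Minimum realized minor allele frequency per marker
#'   (enforced by rejection resampling).
#' @param missing_rate Per-call missingness rate injected by
#'   [degrade_genotypes()].
#' @param het_rate Fraction of sites that receive artifactual heterozygous
#'   calls (defects cluster by site; true inbred genotypes are homozygous).
#' @param low_qual_rate Fraction of sites assigned a QUAL below 20.
#' @param seed Integer seed; identical configurations reproduce bitwise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_accessions, n_markers, n_subpops = 1,
                       admixture_concentration = 0.5, divergence = 0.1,
                       ld_block_size = 10, maf_min = 0.05,
                       missing_rate = 0, het_rate = 0, low_qual_rate = 0,
                       seed = 1L) {
  stopifnot(n_accessions >= 2, n_markers >= 1, n_subpops >= 1,
            admixture_concentration > 0,
            divergence >= 0, divergence < 1,
            ld_block_size >= 1,
            maf_min > 0, maf_min < 0.5,
            missing_rate >= 0, missing_rate < 1,
            het_rate >= 0, het_rate < 1,
            low_qual_rate >= 0, low_qual_rate < 1)
  structure(list(n_accessions = as.integer(n_accessions),
                 n_markers = as.integer(n_markers),
                 n_subpops = as.integer(n_subpops),
                 admixture_concentration = admixture_concentration,
                 divergence = divergence,
                 ld_block_size = as.integer(ld_block_size),
                 maf_min = maf_min, missing_rate = missing_rate,
                 het_rate = het_rate, low_qual_rate = low_qual_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Numeric genotype matrix container
#'
#' Accessions x markers matrix coded 1 = homozygous major allele,
#' -1 = homozygous minor/alternate allele, 0 = heterozygous, NA = missing
#' (only before imputation).
#'
#' @param values Numeric matrix with accession row names and marker column
#'   names.
#' @param marker_meta Data frame of per-marker metadata (one row per column
#'   of `values`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, marker_meta) {
  stopifnot(is.matrix(values), nrow(marker_meta) == ncol(values))
  structure(list(values = values, marker_meta = marker_meta,
                 accession_ids = rownames(values)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers (%.2f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Simulate a complete inbred genotype panel with structure and LD
#'
#' Draws ancestral allele frequencies per marker, diverges them across
#' subpopulations under a Balding-Nichols model with F = `divergence`,
#' assigns each accession Dirichlet admixture proportions, and samples fully
#' homozygous genotypes through a Gaussian copula whose latent variables are
#' shared within LD blocks (AR(1) decay along the block). Markers whose
#' realized minor allele frequency falls below `maf_min` are redrawn.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `geno` (a complete [genotype_matrix()] coded
#'   in \{-1, 1\}), `q_matrix_true` (row-stochastic ancestry matrix),
#'   `subpop_freqs` (K x p allele frequencies), and `block_id` (per-marker LD
#'   block index).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_accessions
  p <- cfg$n_markers
  K <- cfg$n_subpops
  if (ceiling(cfg$maf_min * n) > floor(n / 2)) {
    stop(sprintf(paste0("maf_min = %.3f is unattainable with %d accessions: ",
                        "no minor-genotype count satisfies maf_min <= MAF <= 0.5. ",
                        "Increase n_accessions or lower maf_min."),
                 cfg$maf_min, n))
  }
  set.seed(cfg$seed)
  q <- rdirichlet_mat(n, rep(cfg$admixture_concentration, K))
  block_id <- ((seq_len(p) - 1L) %/% cfg$ld_block_size) + 1L
  # AR(1) latent decay: correlation ~ exp(-3 d / block_size) within a block
  phi <- exp(-3 / cfg$ld_block_size)

  draw_freqs <- function(m) {
    anc <- stats::runif(m, 0.15, 0.85)
    if (cfg$divergence > 0) {
      f <- cfg$divergence
      a <- anc * (1 - f) / f
      b <- (1 - anc) * (1 - f) / f
      matrix(stats::rbeta(K * m, shape1 = rep(a, each = K),
                          shape2 = rep(b, each = K)), nrow = K)
    } else {
      matrix(rep(anc, each = K), nrow = K)
    }
  }

  # latent Gaussian field: one AR(1) chain per accession per block
  latent <- matrix(NA_real_, n, p)
  for (b in unique(block_id)) {
    js <- which(block_id == b)
    z <- stats::rnorm(n)
    for (t in seq_along(js)) {
      if (t == 1L) {
        latent[, js[t]] <- z
      } else {
        z <- phi * z + sqrt(1 - phi^2) * stats::rnorm(n)
        latent[, js[t]] <- z
      }
    }
  }
  u_field <- stats::pnorm(latent)

  subpop_freqs <- draw_freqs(p)
  pij <- q %*% subpop_freqs                  # per-accession freq of allele "b"
  X <- ifelse(u_field < pij, -1, 1)          # inbreds: hom "b" vs hom "a"

  maf_of <- function(col) {
    f <- mean(col == -1)
    min(f, 1 - f)
  }
  for (attempt in seq_len(200)) {
    maf <- apply(X, 2, maf_of)
    bad <- which(maf < cfg$maf_min)
    if (!length(bad)) break
    # redraw frequencies and copula noise for failing markers, keeping the
    # block latent structure via fresh uniforms (independent of neighbours
    # is acceptable for isolated redraws)
    fr <- draw_freqs(length(bad))
    pb <- q %*% fr
    ub <- matrix(stats::runif(n * length(bad)), n)
    X[, bad] <- ifelse(ub < pb, -1, 1)
    subpop_freqs[, bad] <- fr
  }
  maf <- apply(X, 2, maf_of)
  if (any(maf < cfg$maf_min)) {
    stop("could not satisfy maf_min after 200 resampling rounds; ",
         "n_accessions may be too small for the requested maf_min")
  }

  acc_ids <- sprintf("ACC%04d", seq_len(n))
  mk_ids <- sprintf("M%05d", seq_len(p))
  dimnames(X) <- list(acc_ids, mk_ids)
  rownames(q) <- acc_ids
  colnames(q) <- sprintf("SP%d", seq_len(K))
  meta <- data.frame(marker_id = mk_ids,
                     chrom = as.character(((seq_len(p) - 1L) %/%
                                            ceiling(p / 7)) + 1L),
                     pos = (seq_len(p) - 1L) %% ceiling(p / 7) * 100L + 1L,
                     maf = maf, block = block_id,
                     stringsAsFactors = FALSE)
  list(geno = genotype_matrix(X, meta), q_matrix_true = q,
       subpop_freqs = subpop_freqs, block_id = block_id)
}

#' Simulate multi-year phenotypes under a random-effects model
#'
#' Phenotypes follow `y_ij = mu + g_i + E_j + (gE)_ij + e_ij` with genotypic
#' values `g = Z_c u` built from marker effects (`n_qtl` sparse QTL, or all
#' markers in polygenic mode), independent normal year effects, genotype-by-
#' year interactions, and residuals. Variances are scaled so that the
#' entry-mean heritability over the `n_years` simulated years equals `h2`
#' (single observation per accession-year, so r = 1):
#' `h2 = s2G / (s2G + s2GE/j + s2e/j)` with `j = n_years`.
#'
#' @param G A complete [genotype_matrix()].
#' @param n_qtl Number of QTL markers, or `"polygenic"` for effects at every
#'   marker.
#' @param h2 Entry-mean heritability across the simulated years, in (0, 1].
#' @param n_years Number of years (environments); >= 2 for a fittable
#'   genotype-by-year structure.
#' @param gxe_fraction Fraction of the non-genetic variance assigned to the
#'   genotype-by-year interaction (the rest is residual), in `[0, 1)`.
#' @param seed Integer seed.
#' @param trait_name Trait label carried into the records.
#' @return A list with `records` (data frame: accession_id, year_id,
#'   trait_name, value) and `truth` (marker effects, QTL indices, true
#'   breeding values, variance components, `true_h2`).
#' @export
simulate_phenotypes <- function(G, n_qtl = "polygenic", h2, n_years = 3,
                                gxe_fraction = 0.2, seed = 1L,
                                trait_name = "trait") {
  stopifnot(inherits(G, "genotype_matrix"), h2 > 0, h2 <= 1,
            n_years >= 1, gxe_fraction >= 0, gxe_fraction < 1)
  Z <- G$values
  if (anyNA(Z)) stop("G must be complete (impute first)")
  n <- nrow(Z); p <- ncol(Z)
  set.seed(seed)
  if (identical(n_qtl, "polygenic")) {
    qtl <- seq_len(p)
  } else {
    if (n_qtl > p) stop("n_qtl exceeds the number of markers")
    qtl <- sort(sample.int(p, n_qtl))
  }
  u <- numeric(p)
  u[qtl] <- stats::rnorm(length(qtl))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  g <- drop(Zc %*% u)
  s2G <- stats::var(g)
  if (s2G == 0) stop("degenerate genotypes: zero genetic variance")
  noise_total <- if (h2 < 1) n_years * s2G * (1 - h2) / h2 else 0
  s2GE <- gxe_fraction * noise_total
  s2e <- noise_total - s2GE
  s2E_year <- 0.5 * s2G   # year main effect; does not enter heritability
  years <- sprintf("Y%d", seq_len(n_years))
  Ej <- stats::rnorm(n_years, 0, sqrt(s2E_year))
  ge <- matrix(stats::rnorm(n * n_years, 0, sqrt(s2GE)), n, n_years)
  e <- matrix(stats::rnorm(n * n_years, 0, sqrt(s2e)), n, n_years)
  mu <- 10
  vals <- mu + outer(g, Ej, "+") + ge + e
  records <- data.frame(
    accession_id = rep(rownames(Z), times = n_years),
    year_id = rep(years, each = n),
    trait_name = trait_name,
    value = as.vector(vals),
    stringsAsFactors = FALSE)
  truth <- list(true_marker_effects = u, qtl_indices = qtl,
                true_breeding_values = stats::setNames(g, rownames(Z)),
                true_h2 = h2,
                true_sigma2 = c(G = s2G, GE = s2GE, e = s2e,
                                year = s2E_year),
                mu = mu)
  list(records = records, truth = truth)
}
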