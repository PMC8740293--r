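#' Fit the multi-year random-effects model for one trait
#'
#' Fits `y_ij = mu + G_i + E_j + (GE)_ij + e_ij` by REML with genotype,
#' year, and genotype-by-year all random (lme4 backend), and extracts
#' genotype BLUPs, their prediction error variances, and both heritability
#' estimators. With a single record per accession-year cell the interaction
#' and residual variances are not separately identifiable; the interaction
#' term is then dropped and the residual carries their sum (the entry-mean
#' heritability is unchanged, since only `s2GE/j + s2e/(j r)` enters with
#' r = 1).
#'
#' @param records Data frame with columns accession_id, year_id, trait_name,
#'   value (long format; replicated accession-year cells allowed).
#' @param trait Trait name to fit.
#' @return A `trait_model_fit`: variance components `vc` (sigma2_G,
#'   sigma2_E_year, sigma2_GE, sigma2_e), named `blups` and `pev`,
#'   `H2_entry_mean`, `H2_cullis`, `j_years`, `r_harmonic`, `intercept`.
#' @export
fit_pheno_mixed_model <- function(records, trait = records$trait_name[1]) {
  stopifnot(all(c("accession_id", "year_id", "trait_name",
                  "value") %in% names(records)))
  d <- records[records$trait_name == trait & !is.na(records$value), ]
  if (!nrow(d)) stop("no records for trait '", trait, "'")
  d$accession_id <- factor(d$accession_id)
  d$year_id <- factor(d$year_id)
  n_acc <- nlevels(d$accession_id)
  j <- nlevels(d$year_id)
  if (j < 2) stop("at least two years are required to separate genotype ",
                  "and year effects (got ", j, ")")
  if (n_acc < 2) stop("at least two accessions are required")
  if (n_acc < 30) warning("fewer than 30 accessions; variance components ",
                          "will be poorly estimated")
  # degenerate noiseless limit: purely additive accession + year values
  # (zero residual) break the REML iterations, but the fit is closed-form
  ls_fit <- stats::lm(value ~ accession_id + year_id, data = d)
  ls_sigma2 <- suppressWarnings(summary(ls_fit)$sigma^2)
  if (ls_sigma2 < 1e-10 * stats::var(d$value)) {
    eff <- stats::coef(ls_fit)
    acc_eff <- c(0, eff[grep("^accession_id", names(eff))])
    blups <- stats::setNames(acc_eff - mean(acc_eff),
                             levels(d$accession_id))
    vc <- c(sigma2_G = stats::var(blups), sigma2_E_year = NA_real_,
            sigma2_GE = 0, sigma2_e = 0)
    out <- structure(list(trait_name = trait, vc = vc, blups = blups,
                          pev = stats::setNames(rep(0, n_acc),
                                                levels(d$accession_id)),
                          j_years = j, r_harmonic = 1,
                          intercept = mean(d$value), replicated = FALSE,
                          n_accessions = n_acc, lme4_fit = NULL),
                     class = "trait_model_fit")
    out$H2_entry_mean <- 1
    out$H2_cullis <- 1
    return(out)
  }

  replicated <- max(table(d$accession_id, d$year_id)) > 1
  form <- if (replicated) {
    value ~ (1 | accession_id) + (1 | year_id) +
      (1 | accession_id:year_id)
  } else {
    value ~ (1 | accession_id) + (1 | year_id)
  }
  fit <- lme4::lmer(form, data = d,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      check.conv.grad = lme4::.makeCC("warning",
                                                      tol = 0.02,
                                                      relTol = NULL)))
  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vc_tab$vcov[vc_tab$grp == g]
    if (length(v)) v else 0
  }
  s2G <- get_vc("accession_id")
  s2E <- get_vc("year_id")
  s2GE <- if (replicated) get_vc("accession_id:year_id") else 0
  s2e <- vc_tab$vcov[vc_tab$grp == "Residual"]

  re <- lme4::ranef(fit, condVar = TRUE)$accession_id
  blups <- stats::setNames(re[["(Intercept)"]], rownames(re))
  pv <- attr(re, "postVar")
  pev <- stats::setNames(drop(pv[1, 1, ]), rownames(re))

  # r: harmonic mean of per-accession records-per-year
  per_acc <- table(d$accession_id)
  yrs_per_acc <- rowSums(table(d$accession_id, d$year_id) > 0)
  reps <- as.numeric(per_acc) / pmax(yrs_per_acc, 1)
  r_h <- length(reps) / sum(1 / reps)

  vc <- c(sigma2_G = s2G, sigma2_E_year = s2E, sigma2_GE = s2GE,
          sigma2_e = s2e)
  out <- structure(list(trait_name = trait, vc = vc, blups = blups,
                        pev = pev, j_years = j, r_harmonic = r_h,
                        intercept = lme4::fixef(fit)[["(Intercept)"]],
                        replicated = replicated, n_accessions = n_acc,
                        lme4_fit = fit),
                   class = "trait_model_fit")
  out$H2_entry_mean <- heritability_entry_mean(vc, j, r_h)
  out$H2_cullis <- heritability_cullis(out)
  out
}

#' @export
print.trait_model_fit <- function(x, ...) {
  cat(sprintf("trait_model_fit '%s': %d accessions, %d years\n",
              x$trait_name, x$n_accessions, x$j_years))
  cat(sprintf("  sigma2_G = %.4g, sigma2_GE = %.4g, sigma2_e = %.4g\n",
              x$vc[["sigma2_G"]], x$vc[["sigma2_GE"]], x$vc[["sigma2_e"]]))
  cat(sprintf("  H2 (entry-mean) = %.3f, H2 (Cullis) = %.3f\n",
              x$H2_entry_mean, x$H2_cullis))
  invisible(x)
}

#' Entry-mean broad-sense heritability
#'
#' `H2 = s2G / (s2G + s2GE/j + s2e/(j r))` with `j` environments (years)
#' and `r` the harmonic mean of per-accession replicate counts.
#'
#' @param vc Named variance components (needs sigma2_G, sigma2_GE,
#'   sigma2_e).
#' @param j Number of environments (>= 1).
#' @param r Harmonic-mean replicate count (> 0).
#' @return Heritability in `[0, 1]`.
#' @export
heritability_entry_mean <- function(vc, j, r) {
  stopifnot(j >= 1, r > 0)
  s2G <- vc[["sigma2_G"]]; s2GE <- vc[["sigma2_GE"]]
  s2e <- vc[["sigma2_e"]]
  denom <- s2G + s2GE / j + s2e / (j * r)
  if (denom == 0) stop("all variance components are zero; heritability ",
                       "is undefined")
  s2G / denom
}

#' Cullis (PEV-based) generalized heritability
#'
#' `H2 = 1 - mean(PEV) / (md * s2G)` with `md` the mean diagonal of the
#' relationship matrix — the identity here, so `md = 1`. Clipped to
#' `[0, 1]`; defined as 0 when `s2G = 0`.
#'
#' @param fit A `trait_model_fit` (or any list with `pev` and
#'   `vc["sigma2_G"]`).
#' @return Heritability in `[0, 1]`.
#' @export
heritability_cullis <- function(fit) {
  s2G <- fit$vc[["sigma2_G"]]
  if (s2G <= 0) return(0)
  min(max(1 - mean(fit$pev) / s2G, 0), 1)
}
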