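#' GEBV reliability from prediction error variance
#'
#' Computes `1 - PEV / s2g`, the squared-accuracy-scale confidence in a
#' GEBV.
#' Values are clipped to `[0, 1]`, with a warning when PEV numerically
#' exceeds the genetic variance.
#'
#' @param pev Prediction error variance(s), >= 0.
#' @param sigma2g Genetic variance (> 0).
#' @return Reliability value(s) in `[0, 1]`.
#' @export
reliability <- function(pev, sigma2g) {
  if (sigma2g <= 0) stop("sigma2g must be positive")
  stopifnot(all(pev >= 0))
  r <- 1 - pev / sigma2g
  if (any(r < 0)) {
    warning(sum(r < 0), " reliability value(s) below 0 clipped (PEV ",
            "exceeded sigma2g numerically)")
  }
  pmin(pmax(r, 0), 1)
}

#' Predict genotyped but nonphenotyped accessions with reliabilities
#'
#' Fits the marker model once on the phenotyped accessions and carries the
#' nonphenotyped rows as unknowns in the mixed-model equations of the
#' equivalent kernel model, so GEBVs and prediction error variances are
#' defined for every accession. The genetic variance entering the
#' reliability is the marker-based REML estimate from this fit.
#'
#' @param G_all Genotypes for all accessions (phenotyped or not).
#' @param blups Named reference BLUPs for the phenotyped subset.
#' @param model_tag "RRBLUP" (marker kernel ZZ'/c) or "RKHS" (averaged
#'   Gaussian kernels); only these define PEVs through the mixed-model
#'   equations.
#' @param h_set RKHS bandwidths.
#' @return A list with `table` (a `reliability_table` data frame:
#'   accession_id, gebv, pev, reliability, phenotyped, rank_group) and
#'   `fit` (the underlying `gp_fit`).
#' @export
predict_unphenotyped <- function(G_all, blups,
                                 model_tag = c("RRBLUP", "RKHS"),
                                 h_set = 0.5 * c(1 / 5, 1, 5)) {
  model_tag <- match.arg(model_tag)
  Z <- geno_values(G_all)
  obs_ids <- names(blups)
  if (is.null(obs_ids) || !all(obs_ids %in% rownames(Z))) {
    stop("blups must be named by accessions present in G_all")
  }
  if (length(obs_ids) < 30) {
    stop("at least 30 phenotyped accessions are required (got ",
         length(obs_ids), ")")
  }
  obs <- match(obs_ids, rownames(Z))
  y <- unname(blups)
  if (model_tag == "RRBLUP") {
    # centre on the phenotyped (training) rows' means
    cm <- colMeans(Z[obs, , drop = FALSE])
    Zc <- sweep(Z, 2, cm)
    cc <- mean(rowSums(Zc[obs, , drop = FALSE]^2))
    K <- tcrossprod(Zc) / cc
    fit <- fit_gblup(K, y, observed = obs)
  } else {
    K1 <- gaussian_kernel(Z[obs, , drop = FALSE], h_set[1])
    scale <- attr(K1, "distance_scale")
    K_obs <- c(list(unclass(K1)),
               lapply(h_set[-1], function(h)
                 unclass(gaussian_kernel(Z[obs, , drop = FALSE], h,
                                         distance_scale = scale))))
    if (length(h_set) > 1) {
      s2 <- reml_multi(K_obs, y)
      s2b <- s2[seq_along(h_set)]
      if (sum(s2b) <= 1e-10 * stats::var(y)) {
        stop("all kernel variance components collapsed to zero")
      }
      w <- s2b / sum(s2b)
      d2 <- sq_dist(Z)
      Kbar <- 0
      for (r in seq_along(h_set)) {
        Kbar <- Kbar + w[r] * exp(-h_set[r] * d2 / scale)
      }
      fit <- fit_gblup(Kbar, y, observed = obs,
                       fixed_ratio = sum(s2b) / s2[["sigma2_e"]])
    } else {
      Kbar <- unclass(gaussian_kernel(Z, h_set[1], distance_scale = scale))
      fit <- fit_gblup(Kbar, y, observed = obs)
    }
    fit$model_tag <- "RKHS"
  }
  s2g <- fit$vc[["sigma2_g"]]
  tab <- data.frame(accession_id = rownames(Z),
                    gebv = unname(fit$gebv),
                    pev = unname(fit$pev),
                    reliability = reliability(unname(fit$pev), s2g),
                    phenotyped = rownames(Z) %in% obs_ids,
                    rank_group = NA_character_,
                    stringsAsFactors = FALSE)
  class(tab) <- c("reliability_table", "data.frame")
  attr(tab, "sigma2_g") <- s2g
  list(table = tab, fit = fit)
}

#' Flag top and bottom GEBV groups among nonphenotyped accessions
#'
#' Sorts the nonphenotyped rows by GEBV (descending, ties broken by
#' accession ID) and labels the first `group_size` "top50", the last
#' `group_size` "bottom50", and the remainder "intermediate". When fewer
#' than `2 * group_size` nonphenotyped accessions exist the groups shrink
#' proportionally with a warning.
#'
#' @param table A `reliability_table` from [predict_unphenotyped()].
#' @param group_size Rows per extreme group (default 50).
#' @return The table with `rank_group` filled for nonphenotyped rows.
#' @export
rank_and_flag <- function(table, group_size = 50) {
  np <- which(!table$phenotyped)
  if (length(np) < 2 * group_size) {
    group_size <- max(1L, floor(length(np) / 2))
    warning("fewer than twice the group size nonphenotyped; groups ",
            "shrunk to ", group_size)
  }
  ord <- np[order(-table$gebv[np], table$accession_id[np])]
  grp <- rep("intermediate", length(ord))
  grp[seq_len(group_size)] <- "top50"
  grp[seq(length(ord) - group_size + 1, length(ord))] <- "bottom50"
  table$rank_group[ord] <- grp
  table
}

#' Compare observed BLUPs with predicted GEBVs of nonphenotyped accessions
#'
#' Summarizes both distributions (mean, SD, range), tests the mean
#' difference (Welch two-sample t), and flags whether the predicted range
#' lies within the observed range — GEBV shrinkage typically keeps
#' predictions inside the phenotyped accessions' spread.
#'
#' @param observed_blups Reference BLUPs of phenotyped accessions.
#' @param predicted_gebvs GEBVs of nonphenotyped accessions.
#' @return A list: `mean_observed`, `mean_predicted`, `sd_observed`,
#'   `sd_predicted`, `range_observed`, `range_predicted`,
#'   `mean_diff_p_value`, `predicted_within_observed_range`.
#' @export
compare_distributions <- function(observed_blups, predicted_gebvs) {
  stopifnot(length(observed_blups) > 1, length(predicted_gebvs) > 1)
  tt <- stats::t.test(observed_blups, predicted_gebvs)
  ro <- range(observed_blups); rp <- range(predicted_gebvs)
  list(mean_observed = mean(observed_blups),
       mean_predicted = mean(predicted_gebvs),
       sd_observed = stats::sd(observed_blups),
       sd_predicted = stats::sd(predicted_gebvs),
       range_observed = ro, range_predicted = rp,
       mean_diff_p_value = tt$p.value,
       predicted_within_observed_range = rp[1] >= ro[1] && rp[2] <= ro[2])
}
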