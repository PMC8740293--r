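`%||%` <- function(a, b) if (is.null(a)) b else a

geno_values <- function(G) {
  if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
}

#' Fit a genomic prediction model by tag
#'
#' Common entry point used by every cross-validation scheme.
#'
#' @param model_tag One of "RRBLUP", "PLSR", "RF", "BAYESCPI", "RKHS".
#' @param Z Training marker matrix.
#' @param y Training phenotype (BLUP) vector.
#' @param X Optional fixed covariates (RR-BLUP / RKHS only).
#' @param seed Seed forwarded to stochastic fits and tuning folds.
#' @param control Named list of model options (`max_components`,
#'   `n_trees_grid`, `n_iter`, `burn_in`, `thin`, `h_set`).
#' @return A `gp_fit`.
#' @export
fit_gp <- function(model_tag, Z, y, X = NULL, seed = 1L, control = list()) {
  switch(model_tag,
    RRBLUP = fit_rrblup(Z, y, X = X),
    PLSR = {
      if (!is.null(X)) stop("PLSR does not take fixed covariates")
      fit_plsr(Z, y, max_components = control$max_components %||%
                 min(20, nrow(Z) - 1L), seed = seed)
    },
    RF = {
      if (!is.null(X)) stop("random forest does not take fixed covariates")
      fit_rf(Z, y, n_trees_grid = control$n_trees_grid %||% c(100, 300, 500),
             seed = seed)
    },
    BAYESCPI = {
      if (!is.null(X)) stop("BayesC-pi does not take fixed covariates")
      fit_bayescpi(Z, y, n_iter = control$n_iter %||% 20000,
                   burn_in = control$burn_in %||% 5000,
                   thin = control$thin %||% 5, seed = seed)
    },
    RKHS = fit_rkhs_multikernel(Z, y,
                                h_set = control$h_set %||%
                                  0.5 * c(1 / 5, 1, 5), X = X),
    stop("unknown model_tag '", model_tag, "'"))
}

#' Cross-validation scheme descriptor
#'
#' @param kind "random_split" (train_frac/validation) or "kfold".
#' @param train_frac Training fraction for random splits (default 0.8).
#' @param k Fold count for k-fold schemes (default 5).
#' @param reps Number of replicates (default 20).
#' @param seed Scheme seed; splits are drawn on lexicographically sorted
#'   accession IDs, so results do not depend on input row order.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("random_split", "kfold"), train_frac = 0.8,
                      k = 5, reps = 20, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(train_frac > 0, train_frac < 1, k >= 2, reps >= 1)
  structure(list(kind = kind, train_frac = train_frac, k = as.integer(k),
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Predictive ability: correlation with reference breeding values
#'
#' Pearson correlation between model GEBVs and the reference (full-data
#' mixed-model BLUP) breeding values of the validation accessions.
#'
#' @param gebv_val Predicted GEBVs.
#' @param reference_ebv_val Reference values, same accessions.
#' @return The correlation, or `NA` (with a warning) when either vector has
#'   zero variance.
#' @export
predictive_ability <- function(gebv_val, reference_ebv_val) {
  stopifnot(length(gebv_val) == length(reference_ebv_val),
            length(gebv_val) >= 3)
  if (!all(is.finite(gebv_val)) || !all(is.finite(reference_ebv_val))) {
    warning("non-finite values; ability recorded as NA")
    return(NA_real_)
  }
  if (stats::var(gebv_val) == 0 || stats::var(reference_ebv_val) == 0) {
    warning("zero variance in predictions or reference; ability recorded ",
            "as NA")
    return(NA_real_)
  }
  stats::cor(gebv_val, reference_ebv_val)
}

#' Percentile bootstrap confidence interval for a mean ability
#'
#' Resamples the replicate abilities with replacement `B` times and takes
#' percentile bounds of the resampled means.
#'
#' @param abilities Replicate ability vector (length >= 2; NAs dropped).
#' @param B Bootstrap samples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(abilities, B = 10000, level = 0.95, seed = 1L) {
  a <- abilities[!is.na(abilities)]
  stopifnot(length(a) >= 2)
  set.seed(seed)
  idx <- matrix(sample.int(length(a), length(a) * B, replace = TRUE),
                nrow = B)
  means <- rowMeans(matrix(a[idx], nrow = B))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

new_cv_report <- function(model_tag, scheme_kind, abilities, rep_seeds,
                          ci_seed, extra = list()) {
  ok <- abilities[!is.na(abilities)]
  rep <- c(list(model_tag = model_tag, scheme = scheme_kind,
                abilities = abilities,
                mean_ability = mean(ok),
                ci95 = if (length(ok) >= 2) {
                  bootstrap_ci(ok, seed = ci_seed)
                } else c(NA_real_, NA_real_),
                n_failed = sum(is.na(abilities)),
                per_rep_seeds = rep_seeds), extra)
  structure(rep, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s, %s]: mean ability %.3f (95%% CI %.3f-%.3f, %d reps%s)\n",
              x$model_tag, x$scheme, x$mean_ability, x$ci95[1], x$ci95[2],
              length(x$abilities),
              if (x$n_failed) sprintf(", %d failed", x$n_failed) else ""))
  invisible(x)
}

align_geno_blups <- function(G, blups) {
  Z <- geno_values(G)
  if (is.null(names(blups))) {
    stopifnot(length(blups) == nrow(Z))
    names(blups) <- rownames(Z)
  }
  ids <- sort(intersect(rownames(Z), names(blups)))
  if (length(ids) < 3) stop("fewer than 3 accessions shared between ",
                            "genotypes and BLUPs")
  list(Z = Z[ids, , drop = FALSE], y = blups[ids], ids = ids)
}

rep_seeds_for <- function(seed, reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

score_split <- function(model_tag, Z, y, train, val, seed, control,
                        X = NULL, X_builder = NULL) {
  Xtr <- Xval <- NULL
  if (!is.null(X_builder)) {
    xb <- X_builder(train, val)
    Xtr <- xb$train; Xval <- xb$val
  } else if (!is.null(X)) {
    Xtr <- X[train, , drop = FALSE]; Xval <- X[val, , drop = FALSE]
  }
  fit <- fit_gp(model_tag, Z[train, , drop = FALSE], y[train], X = Xtr,
                seed = seed, control = control)
  pred <- predict(fit, Z[val, , drop = FALSE], X_new = Xval)
  predictive_ability(pred, y[val])
}

run_one_rep <- function(model_tag, Z, y, scheme, rep_seed, control,
                        X = NULL, X_builder = NULL) {
  n <- nrow(Z)
  set.seed(rep_seed)
  if (scheme$kind == "random_split") {
    n_train <- round(scheme$train_frac * n)
    train <- sort(sample.int(n, n_train))
    val <- setdiff(seq_len(n), train)
    score_split(model_tag, Z, y, train, val, rep_seed, control, X,
                X_builder)
  } else {
    folds <- sample(rep_len(seq_len(scheme$k), n))
    fa <- vapply(seq_len(scheme$k), function(fo) {
      score_split(model_tag, Z, y, which(folds != fo), which(folds == fo),
                  rep_seed + fo, control, X, X_builder)
    }, numeric(1))
    mean(fa, na.rm = TRUE)
  }
}

#' Run a replicated cross-validation for one model
#'
#' For each replicate the split is drawn by the scheme (seeded, on sorted
#' accession IDs), the model is fitted on the training set only (centring
#' and any hyperparameter tuning happen inside the fit), validation
#' accessions are predicted, and the predictive ability against the
#' reference BLUPs is recorded. Failed replicates are kept as NA and
#' counted.
#'
#' @param model_tag Model name (see [fit_gp()]).
#' @param G Genotypes ([genotype_matrix()] or matrix).
#' @param blups Named reference breeding values (full-data mixed-model
#'   BLUPs).
#' @param scheme A [cv_scheme()].
#' @param control Model options forwarded to [fit_gp()].
#' @return A `cv_report`.
#' @export
run_cv <- function(model_tag, G, blups, scheme = cv_scheme(),
                   control = list()) {
  al <- align_geno_blups(G, blups)
  seeds <- rep_seeds_for(scheme$seed, scheme$reps)
  abilities <- vapply(seq_len(scheme$reps), function(rr) {
    tryCatch(run_one_rep(model_tag, al$Z, al$y, scheme, seeds[rr], control),
             error = function(e) {
               warning("replicate ", rr, " failed: ", conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  new_cv_report(model_tag, scheme$kind, abilities, seeds,
                ci_seed = scheme$seed + 1L)
}

#' Predictive ability as a function of training population size
#'
#' Per replicate, a validation set of `val_size` accessions is drawn
#' without replacement; the training set then grows sequentially from the
#' remaining accessions so the sets are nested across sizes within a
#' replicate.
#'
#' @param model_tag Model name.
#' @param G Genotypes.
#' @param blups Named reference BLUPs.
#' @param sizes Training sizes (default 50 to 175 by 25).
#' @param val_size Validation-set size (default 50).
#' @param reps Replicates (default 20).
#' @param seed Seed.
#' @param control Model options.
#' @return Named list of `cv_report`, one per size; each also records the
#'   nested training sets' first replicate for inspection.
#' @export
training_size_curve <- function(model_tag, G, blups,
                                sizes = seq(50, 175, by = 25),
                                val_size = 50, reps = 20, seed = 1L,
                                control = list()) {
  al <- align_geno_blups(G, blups)
  n <- nrow(al$Z)
  if (max(sizes) + val_size > n) {
    stop("max(sizes) + val_size exceeds the ", n, " available accessions")
  }
  seeds <- rep_seeds_for(seed, reps)
  ab <- matrix(NA_real_, reps, length(sizes),
               dimnames = list(NULL, sizes))
  train_sets_rep1 <- vector("list", length(sizes))
  for (rr in seq_len(reps)) {
    set.seed(seeds[rr])
    perm <- sample.int(n)
    val <- perm[seq_len(val_size)]
    pool <- perm[-seq_len(val_size)]
    for (si in seq_along(sizes)) {
      train <- sort(pool[seq_len(sizes[si])])     # nested by construction
      if (rr == 1L) train_sets_rep1[[si]] <- al$ids[train]
      ab[rr, si] <- tryCatch(
        score_split(model_tag, al$Z, al$y, train, sort(val), seeds[rr],
                    control),
        error = function(e) NA_real_)
    }
  }
  out <- lapply(seq_along(sizes), function(si) {
    new_cv_report(model_tag, "training_size", ab[, si], seeds,
                  ci_seed = seed + 1L,
                  extra = list(size = sizes[si],
                               train_set_rep1 = train_sets_rep1[[si]]))
  })
  names(out) <- sizes
  out
}

#' Predictive ability as a function of marker density
#'
#' Per replicate, each marker subset is drawn uniformly without
#' replacement and scored by k-fold cross-validation (folds shared across
#' subset sizes within a replicate, so the curve is paired).
#'
#' @param model_tag Model name.
#' @param G Genotypes.
#' @param blups Named reference BLUPs.
#' @param counts Marker-subset sizes; counts above the available marker
#'   number are clipped with a warning.
#' @param reps Replicates (default 20).
#' @param k Folds (default 5).
#' @param seed Seed.
#' @param control Model options.
#' @return Named list of `cv_report`, one per marker count.
#' @export
marker_density_curve <- function(model_tag, G, blups,
                                 counts = c(1000, 5000, 10000, 15000,
                                            20000, 25000, 30000),
                                 reps = 20, k = 5, seed = 1L,
                                 control = list()) {
  al <- align_geno_blups(G, blups)
  p <- ncol(al$Z)
  if (any(counts > p)) {
    warning("marker counts above ", p, " clipped to ", p)
    counts <- pmin(counts, p)
  }
  counts <- sort(unique(counts))
  n <- nrow(al$Z)
  seeds <- rep_seeds_for(seed, reps)
  ab <- matrix(NA_real_, reps, length(counts),
               dimnames = list(NULL, counts))
  for (rr in seq_len(reps)) {
    set.seed(seeds[rr])
    folds <- sample(rep_len(seq_len(k), n))
    for (ci in seq_along(counts)) {
      mk <- sort(sample.int(p, counts[ci]))
      fa <- vapply(seq_len(k), function(fo) {
        tryCatch(score_split(model_tag, al$Z[, mk, drop = FALSE], al$y,
                             which(folds != fo), which(folds == fo),
                             seeds[rr] + fo, control),
                 error = function(e) NA_real_)
      }, numeric(1))
      ab[rr, ci] <- mean(fa, na.rm = TRUE)
    }
  }
  out <- lapply(seq_along(counts), function(ci) {
    new_cv_report(model_tag, "marker_density", ab[, ci], seeds,
                  ci_seed = seed + 1L, extra = list(n_markers = counts[ci]))
  })
  names(out) <- counts
  out
}

#' Cross-validation with population-structure covariates
#'
#' Adds structure covariates as fixed effects to the RR-BLUP model:
#' `"pc10"` uses the top principal-component scores computed on the
#' training genotypes only and projected onto the validation rows;
#' `"qmatrix"` uses K-1 columns of an externally estimated admixture
#' Q-matrix; `"sp_factor"` uses subpopulation-indicator contrasts. The
#' report carries the variance in the reference BLUPs explained by the
#' covariates (R-squared on the full data).
#'
#' @param model_tag "RRBLUP" (or "RKHS"); other models take no covariates.
#' @param G Genotypes.
#' @param blups Named reference BLUPs.
#' @param mode One of "none", "pc10", "qmatrix", "sp_factor".
#' @param structure A `structure_info` (needed unless mode = "none").
#' @param scheme A [cv_scheme()] (default five-fold, 20 reps).
#' @param n_pc Number of PCs for mode "pc10".
#' @param control Model options.
#' @return A `cv_report` with extra element `var_explained`.
#' @export
structure_adjusted_cv <- function(model_tag, G, blups,
                                  mode = c("none", "pc10", "qmatrix",
                                           "sp_factor"),
                                  structure = NULL,
                                  scheme = cv_scheme("kfold", k = 5,
                                                     reps = 20),
                                  n_pc = 10, control = list()) {
  mode <- match.arg(mode)
  if (mode == "none") return(run_cv(model_tag, G, blups, scheme, control))
  if (is.null(structure) && mode != "pc10") {
    stop("mode '", mode, "' requires a structure_info object")
  }
  if (!model_tag %in% c("RRBLUP", "RKHS")) {
    stop("structure covariates enter as fixed effects; use RRBLUP or RKHS")
  }
  al <- align_geno_blups(G, blups)
  n <- nrow(al$Z)

  full_cov <- switch(mode,
    pc10 = {
      pca <- pca_genotypes(al$Z, n_pc = min(n_pc, n - 2L))
      pca$pc_scores
    },
    qmatrix = {
      q <- structure$q_matrix[al$ids, , drop = FALSE]
      q[, -ncol(q), drop = FALSE]
    },
    sp_factor = {
      lab <- factor(structure$labels[al$ids])
      if (nlevels(lab) < 2) stop("subpopulation factor has a single level")
      stats::model.matrix(~lab)[, -1, drop = FALSE]
    })
  r2 <- summary(stats::lm(al$y ~ full_cov))$r.squared

  X_builder <- if (mode == "pc10") {
    function(train, val) {
      cm <- colMeans(al$Z[train, , drop = FALSE])
      Ztr <- sweep(al$Z[train, , drop = FALSE], 2, cm)
      npc <- min(n_pc, length(train) - 2L)
      sv <- svd(Ztr, nu = 0, nv = npc)
      loads <- sv$v
      list(train = Ztr %*% loads,
           val = sweep(al$Z[val, , drop = FALSE], 2, cm) %*% loads)
    }
  } else {
    function(train, val) {
      list(train = full_cov[train, , drop = FALSE],
           val = full_cov[val, , drop = FALSE])
    }
  }

  seeds <- rep_seeds_for(scheme$seed, scheme$reps)
  abilities <- vapply(seq_len(scheme$reps), function(rr) {
    tryCatch(run_one_rep(model_tag, al$Z, al$y, scheme, seeds[rr], control,
                         X_builder = X_builder),
             error = function(e) {
               warning("replicate ", rr, " failed: ", conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  new_cv_report(model_tag, paste0("structure_", mode), abilities, seeds,
                ci_seed = scheme$seed + 1L,
                extra = list(var_explained = r2, mode = mode))
}

#' Within- and across-subpopulation prediction
#'
#' `"within"` restricts cross-validation to the target subpopulation's
#' members; `"leave_one_sp_out"` trains on all non-members and predicts all
#' members in one deterministic split. With `sizes`, training subsets of
#' increasing size are drawn from the non-members per replicate.
#'
#' @param model_tag Model name.
#' @param G Genotypes.
#' @param blups Named reference BLUPs.
#' @param labels Named subpopulation labels (e.g. from [assign_subpops()]).
#' @param target_sp Target subpopulation label.
#' @param mode "within" or "leave_one_sp_out".
#' @param sizes Optional training sizes for the leave-one-SP-out variant.
#' @param reps Replicates for within-mode / sizes variant.
#' @param seed Seed.
#' @param control Model options.
#' @return A `cv_report` (or a list of them, one per size).
#' @export
subpop_prediction <- function(model_tag, G, blups, labels, target_sp,
                              mode = c("within", "leave_one_sp_out"),
                              sizes = NULL, reps = 20, seed = 1L,
                              control = list()) {
  mode <- match.arg(mode)
  al <- align_geno_blups(G, blups)
  lab <- labels[al$ids]
  members <- which(lab == target_sp)
  if (!length(members)) stop("no accessions labelled '", target_sp, "'")
  if (mode == "within") {
    if (length(members) < 10) {
      stop("within-subpopulation prediction needs >= 10 members (got ",
           length(members), ")")
    }
    return(run_cv(model_tag,
                  al$Z[members, , drop = FALSE], al$y[members],
                  cv_scheme("kfold", k = 5, reps = reps, seed = seed),
                  control))
  }
  others <- setdiff(seq_len(nrow(al$Z)), members)
  if (!length(others)) stop("leave-one-SP-out is undefined: every ",
                            "accession belongs to '", target_sp, "'")
  if (is.null(sizes)) {
    a <- score_split(model_tag, al$Z, al$y, others, members, seed, control)
    return(new_cv_report(model_tag, "leave_one_sp_out", a, seed,
                         ci_seed = seed + 1L,
                         extra = list(target_sp = target_sp)))
  }
  stopifnot(max(sizes) <= length(others))
  seeds <- rep_seeds_for(seed, reps)
  out <- lapply(sizes, function(sz) {
    ab <- vapply(seq_len(reps), function(rr) {
      set.seed(seeds[rr])
      train <- sort(sample(others, sz))
      tryCatch(score_split(model_tag, al$Z, al$y, train, members,
                           seeds[rr], control),
               error = function(e) NA_real_)
    }, numeric(1))
    new_cv_report(model_tag, "leave_one_sp_out_size", ab, seeds,
                  ci_seed = seed + 1L,
                  extra = list(target_sp = target_sp, size = sz))
  })
  names(out) <- sizes
  out
}
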