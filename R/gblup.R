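#' Fit a single-kernel GBLUP mixed model by REML
#'
#' Fits `y = X b + g + e` with `g ~ N(0, s2g K)` over all rows of `K` and
#' `e ~ N(0, s2e I)` on the observed rows. The restricted likelihood is
#' profiled through the eigendecomposition of the observed block of `K` and
#' maximized over the variance ratio by one-dimensional optimization. GEBVs
#' and prediction error variances (from the mixed-model-equation coefficient
#' inverse, accounting for fixed-effect estimation) are returned for every
#' row of `K`, including rows with no phenotype.
#'
#' @param K n x n symmetric positive semi-definite relationship/kernel
#'   matrix (all accessions, phenotyped or not).
#' @param y Phenotype (BLUP) vector for the observed rows.
#' @param X Fixed-effect design for the observed rows (default intercept).
#' @param observed Indices of rows of `K` carrying `y` (default all).
#' @param fixed_ratio Optional fixed s2g/s2e, skipping REML.
#' @return A `gp_fit` with model_tag "GBLUP": `vc`, `beta`, `gebv` (all
#'   rows, includes the intercept), `pev`, `alpha` (for kernel-extension
#'   prediction), and the REML log-likelihood.
#' @export
fit_gblup <- function(K, y, X = NULL, observed = NULL, fixed_ratio = NULL) {
  K <- unclass(K)
  n_all <- nrow(K)
  if (is.null(observed)) observed <- seq_len(n_all)
  n <- length(observed)
  stopifnot(length(y) == n, n >= 2)
  if (stats::var(y) == 0) stop("phenotypes have zero variance")
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  Ko <- K[observed, observed, drop = FALSE]
  if (max(abs(Ko - t(Ko))) > 1e-8) stop("K is not symmetric")
  eig <- eigen(Ko, symmetric = TRUE)
  d <- eig$values
  if (min(d) < -1e-6 * max(abs(d), 1)) {
    stop("K is not positive semi-definite (min eigenvalue ",
         signif(min(d), 3), ")")
  }
  d <- pmax(d, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  reml_neg_ll <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- lambda * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    b <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
    if (is.null(b)) return(1e10)
    r <- ys - Xs %*% b
    rss <- sum(r^2 * w)
    s2e <- rss / (n - q)
    0.5 * (sum(log(v)) + (n - q) * log(s2e) +
           determinant(XtWX, logarithm = TRUE)$modulus + (n - q))
  }
  if (is.null(fixed_ratio)) {
    opt <- stats::optimize(reml_neg_ll, interval = c(-18, 18))
    lambda <- exp(opt$minimum)
    loglik <- -opt$objective
  } else {
    stopifnot(fixed_ratio > 0)
    # extreme ratios (a near-zero residual component upstream) make the
    # weighted normal equations singular; cap at a numerically safe value
    lambda <- min(fixed_ratio, 1e8)
    loglik <- -reml_neg_ll(log(lambda))
  }
  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  b <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% b
  s2e <- sum(r^2 * w) / (n - q)
  s2g <- lambda * s2e

  # V^{-1} and P = V^{-1} - V^{-1} X (X'V^{-1}X)^{-1} X'V^{-1}, V = s2g Ko + s2e I
  Vinv <- U %*% (t(U) * (w / s2e))
  VinvX <- Vinv %*% X
  P <- Vinv - VinvX %*% solve(crossprod(X, VinvX), t(VinvX))
  resid <- y - X %*% b
  alpha <- drop(Vinv %*% resid)              # V^{-1}(y - Xb)
  g_all <- s2g * drop(K[, observed, drop = FALSE] %*% alpha)
  KP <- K[, observed, drop = FALSE] %*% P
  pev <- s2g * diag(K) - s2g^2 *
    rowSums(KP * K[, observed, drop = FALSE])
  pev <- pmax(pev, 0)
  intercept <- if (q == 1 && all(X == 1)) b[1] else NA_real_
  gebv <- (if (!is.na(intercept)) intercept else 0) + g_all
  names(gebv) <- rownames(K)
  structure(list(model_tag = "GBLUP",
                 vc = c(sigma2_g = s2g, sigma2_e = s2e),
                 beta = drop(b), intercept = intercept,
                 gebv = gebv, g = g_all, pev = pev,
                 train_gebv = gebv[observed], train_pev = pev[observed],
                 alpha = alpha, observed = observed, loglik = loglik,
                 n_train = n),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit [%s]: n_train = %d, sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$model_tag, x$n_train, x$vc[["sigma2_g"]],
              x$vc[["sigma2_e"]]))
  invisible(x)
}

#' Fit ridge-regression BLUP (RR-BLUP) on markers
#'
#' All marker effects share one normal distribution `u ~ N(0, I s2u)`.
#' Columns are centred on training means; variance components come from
#' REML on the marker-derived relationship matrix `K = Zc Zc' / c` with
#' `c = mean(diag(Zc Zc'))`, and marker effects are recovered through the
#' ridge identity `u = Zc'(Zc Zc' + (s2e/s2u) I)^{-1}(y - Xb)`, which makes
#' the fit exactly equivalent to GBLUP on `K`.
#'
#' @param Z Marker matrix (accessions x markers), complete.
#' @param y Phenotype (BLUP) vector aligned to rows of `Z`.
#' @param X Optional fixed-effect design (intercept added automatically).
#' @param fixed_lambda Optional fixed marker-space ridge parameter
#'   `lambda = s2e/s2u`, skipping REML.
#' @return A `gp_fit` with model_tag "RRBLUP", marker effects in
#'   `marker_effects`, stored column means for prediction, and PEVs from
#'   the equivalent GBLUP mixed-model equations.
#' @export
fit_rrblup <- function(Z, y, X = NULL, fixed_lambda = NULL) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(y))
  col_means <- colMeans(Z)
  Zc <- sweep(Z, 2, col_means)
  cc <- mean(rowSums(Zc^2))
  if (cc == 0) stop("all markers are monomorphic")
  K <- tcrossprod(Zc) / cc
  Xd <- cbind(`(Intercept)` = rep(1, nrow(Z)), X)
  fixed_ratio <- if (!is.null(fixed_lambda)) cc / fixed_lambda else NULL
  fit <- fit_gblup(K, y, X = Xd, fixed_ratio = fixed_ratio)
  s2g <- fit$vc[["sigma2_g"]]
  u <- drop(crossprod(Zc, fit$alpha)) * s2g / cc
  fit$model_tag <- "RRBLUP"
  fit$marker_effects <- u
  fit$sigma2_u <- s2g / cc
  fit$col_means <- col_means
  fit$intercept <- fit$beta[1]
  fit$beta_cov <- if (ncol(Xd) > 1) fit$beta[-1] else NULL
  fit$gebv <- fit$beta[1] + drop(Zc %*% u) +
    (if (!is.null(X)) drop(X %*% fit$beta_cov) else 0)
  names(fit$gebv) <- rownames(Z)
  fit$train_gebv <- fit$gebv
  fit
}

#' Predict GEBVs for new accessions from a fitted model
#'
#' Marker-effect models (RR-BLUP, BayesC-pi, PLSR) centre `Z_new` with the
#' stored training column means and apply the learned effects; kernel
#' models (GBLUP on a marker kernel, RKHS) extend the mixed-model equations
#' through the cross-kernel with the training rows; random forests predict
#' through the ensemble.
#'
#' @param object A `gp_fit`.
#' @param Z_new New accessions x markers matrix over the fit's marker set.
#' @param X_new Optional fixed-covariate values for the new rows (models
#'   fitted with covariates).
#' @param ... Unused.
#' @return Named GEBV vector (includes the fitted intercept).
#' @export
predict.gp_fit <- function(object, Z_new, X_new = NULL, ...) {
  Z_new <- as.matrix(Z_new)
  fit <- object
  base <- switch(fit$model_tag,
    RRBLUP = , BAYESCPI = {
      if (ncol(Z_new) != length(fit$marker_effects)) {
        stop("marker-set mismatch: fit has ", length(fit$marker_effects),
             " markers, Z_new has ", ncol(Z_new))
      }
      Zc <- sweep(Z_new, 2, fit$col_means)
      fit$intercept + drop(Zc %*% fit$marker_effects)
    },
    PLSR = {
      Zc <- sweep(Z_new, 2, fit$col_means)
      fit$y_mean + drop(Zc %*% fit$coef)
    },
    RF = {
      colnames(Z_new) <- fit$feature_names
      unname(stats::predict(fit$forest, as.data.frame(Z_new)))
    },
    RKHS = {
      Kc <- cross_kernel_bar(fit, Z_new)
      fit$intercept + fit$sigma2_g_bar * drop(Kc %*% fit$alpha)
    },
    GBLUP = stop("GBLUP fits predict through rows of K; refit with the ",
                 "new accessions included (observed = training rows)"),
    stop("unknown model_tag ", fit$model_tag))
  if (!is.null(fit$beta_cov) && length(fit$beta_cov)) {
    if (is.null(X_new)) stop("fit used fixed covariates; supply X_new")
    base <- base + drop(as.matrix(X_new) %*% fit$beta_cov)
  }
  stats::setNames(base, rownames(Z_new))
}
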