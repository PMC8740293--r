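pls1_nipals <- function(Zc, yc, ncomp) {
  # univariate-response partial least squares, NIPALS deflation
  p <- ncol(Zc)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  E <- Zc; f <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q_ <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_
  }
  list(W = W[, seq_len(ncomp), drop = FALSE],
       P = P[, seq_len(ncomp), drop = FALSE],
       q = q[seq_len(ncomp)], ncomp = ncomp)
}

pls1_coef <- function(dec, a) {
  # regression coefficients using the first a components
  W <- dec$W[, seq_len(a), drop = FALSE]
  P <- dec$P[, seq_len(a), drop = FALSE]
  drop(W %*% solve(crossprod(P, W), dec$q[seq_len(a)]))
}

#' Fit partial least squares regression on markers
#'
#' Latent components are extracted iteratively, each maximizing the
#' covariance between its score and the deflated response. The number of
#' components is chosen by five-fold cross-validation minimizing prediction
#' error, as is conventional; it must stay below the number of training
#' observations.
#'
#' @param Z Marker matrix.
#' @param y Phenotype (BLUP) vector.
#' @param max_components Largest component count considered.
#' @param seed Seed for the CV folds.
#' @return A `gp_fit` with model_tag "PLSR": chosen `ncomp`, regression
#'   coefficients, and stored centring for prediction.
#' @export
fit_plsr <- function(Z, y, max_components = 20, seed = 1L) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(length(y) == n)
  if (max_components >= n) {
    stop("max_components must be less than the number of observations (",
         max_components, " >= ", n, ")")
  }
  max_components <- min(max_components, ncol(Z))
  col_means <- colMeans(Z)
  y_mean <- mean(y)
  Zc <- sweep(Z, 2, col_means)
  yc <- y - y_mean
  set.seed(seed)
  folds <- sample(rep_len(seq_len(5), n))
  press <- numeric(max_components)
  for (fo in seq_len(5)) {
    tr <- folds != fo
    cm <- colMeans(Z[tr, , drop = FALSE]); ym <- mean(y[tr])
    dec <- pls1_nipals(sweep(Z[tr, , drop = FALSE], 2, cm), y[tr] - ym,
                       min(max_components, sum(tr) - 1L))
    Zv <- sweep(Z[!tr, , drop = FALSE], 2, cm)
    for (a in seq_len(dec$ncomp)) {
      pred <- ym + drop(Zv %*% pls1_coef(dec, a))
      press[a] <- press[a] + sum((y[!tr] - pred)^2)
    }
    if (dec$ncomp < max_components) {
      press[(dec$ncomp + 1):max_components] <-
        press[(dec$ncomp + 1):max_components] + sum((y[!tr] - ym)^2) * 10
    }
  }
  # smallest component count within numerical reach of the minimum PRESS,
  # so exact low-rank signals do not drift to larger models
  ncomp <- which(press <= min(press) + 1e-6 * sum(yc^2))[1]
  dec <- pls1_nipals(Zc, yc, ncomp)
  coef <- pls1_coef(dec, dec$ncomp)
  gebv <- y_mean + drop(Zc %*% coef)
  structure(list(model_tag = "PLSR", ncomp = dec$ncomp, coef = coef,
                 col_means = col_means, y_mean = y_mean,
                 intercept = y_mean,
                 weights1 = dec$W[, 1],
                 gebv = stats::setNames(gebv, rownames(Z)),
                 train_gebv = stats::setNames(gebv, rownames(Z)),
                 press = press, n_train = n),
            class = "gp_fit")
}

#' Fit a random forest genomic prediction model
#'
#' An ensemble of regression trees on bootstrap samples with random feature
#' subsetting (mtry = p/3, minimum node size 5). The tree count is chosen
#' from `n_trees_grid` by five-fold cross-validation minimizing prediction
#' error: one forest of `max(n_trees_grid)` trees is grown per fold and
#' truncated ensembles are scored from the per-tree predictions.
#'
#' @param Z Marker matrix.
#' @param y Phenotype (BLUP) vector.
#' @param n_trees_grid Candidate tree counts.
#' @param seed Seed (forest growth and folds).
#' @return A `gp_fit` with model_tag "RF" holding the fitted forest.
#' @export
fit_rf <- function(Z, y, n_trees_grid = c(100, 300, 500), seed = 1L) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(length(y) == n)
  if (n < 20) stop("random forest requires at least 20 training accessions")
  feature_names <- paste0("m", seq_len(ncol(Z)))
  colnames(Z) <- feature_names
  df <- as.data.frame(Z)
  mtry <- max(1L, floor(ncol(Z) / 3))
  set.seed(seed)
  best_ntree <- max(n_trees_grid)
  if (length(n_trees_grid) > 1) {
    folds <- sample(rep_len(seq_len(5), n))
    sse <- stats::setNames(numeric(length(n_trees_grid)),
                           n_trees_grid)
    for (fo in seq_len(5)) {
      tr <- folds != fo
      rf <- suppressWarnings(randomForest::randomForest(
        x = df[tr, , drop = FALSE], y = y[tr],
        ntree = max(n_trees_grid), mtry = mtry, nodesize = 5))
      pa <- stats::predict(rf, df[!tr, , drop = FALSE],
                           predict.all = TRUE)$individual
      for (g in seq_along(n_trees_grid)) {
        pred <- rowMeans(pa[, seq_len(n_trees_grid[g]), drop = FALSE])
        sse[g] <- sse[g] + sum((y[!tr] - pred)^2)
      }
    }
    best_ntree <- n_trees_grid[which.min(sse)]
  }
  forest <- suppressWarnings(
    randomForest::randomForest(x = df, y = y, ntree = best_ntree,
                               mtry = mtry, nodesize = 5))
  gebv <- unname(stats::predict(forest, df))
  structure(list(model_tag = "RF", forest = forest, ntree = best_ntree,
                 feature_names = feature_names,
                 gebv = stats::setNames(gebv, rownames(Z)),
                 train_gebv = stats::setNames(gebv, rownames(Z)),
                 intercept = mean(y), n_train = n),
            class = "gp_fit")
}
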