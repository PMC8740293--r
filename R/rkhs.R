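sq_dist <- function(A, B = A) {
  # squared Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d, 0)
}

#' Gaussian genetic-distance kernel
#'
#' `K[i, i'] = exp(-h d2[i, i'] / s)` with `d2` the squared Euclidean
#' genotype distance over markers and `s` the mean off-diagonal squared
#' distance (recorded as `distance_scale`), so the printed bandwidths act
#' on a standardized distance. The diagonal is exactly 1.
#'
#' @param Z Complete marker matrix.
#' @param h Bandwidth (> 0).
#' @param distance_scale Optional precomputed scale (reused when building
#'   cross-kernels for prediction).
#' @return A `kernel_matrix`: the n x n kernel with attributes `bandwidth`
#'   and `distance_scale`.
#' @export
gaussian_kernel <- function(Z, h, distance_scale = NULL) {
  stopifnot(h > 0)
  Z <- as.matrix(Z)
  if (anyNA(Z)) stop("Z must be complete")
  d2 <- sq_dist(Z)
  if (is.null(distance_scale)) {
    n <- nrow(Z)
    distance_scale <- if (n > 1) sum(d2) / (n * (n - 1)) else 1
    if (distance_scale == 0) distance_scale <- 1
  }
  K <- exp(-h * d2 / distance_scale)
  diag(K) <- 1
  structure(K, bandwidth = h, distance_scale = distance_scale,
            class = c("kernel_matrix", "matrix"))
}

# restricted log-likelihood for a multi-component model
# V = sum_r s2[r] K_r + s2[r+1] I  (variances on log scale in `par`)
reml_ll_multi <- function(par, K_list, y, X) {
  s2 <- exp(par)
  n <- length(y)
  V <- diag(s2[length(s2)], n)
  for (r in seq_along(K_list)) V <- V + s2[r] * K_list[[r]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  b <- solve(XtViX, crossprod(Vi_X, y))
  Py <- Vi_y - Vi_X %*% b
  -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus +
          sum(y * Py))
}

reml_multi <- function(K_list, y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  r <- length(K_list)
  init <- log(rep(stats::var(y) / (r + 1), r + 1))
  opt <- stats::optim(init, reml_ll_multi, K_list = K_list, y = y, X = X,
                      method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 2000,
                                     reltol = 1e-10))
  stats::setNames(exp(opt$par), c(paste0("sigma2_k", seq_len(r)),
                                  "sigma2_e"))
}

#' Fit a multi-kernel RKHS regression
#'
#' Builds one Gaussian kernel per bandwidth in `h_set` (sharing one
#' distance scale), estimates a variance component per kernel by
#' multi-component REML, forms the variance-weighted averaged kernel
#' `Kbar = sum_r K_r s2_r / sum_r s2_r`, and obtains final GEBVs and PEVs
#' from GBLUP on `Kbar` at the estimated total kernel variance.
#'
#' @param Z Complete marker matrix.
#' @param y Phenotype (BLUP) vector.
#' @param h_set Bandwidths; default `0.5 * c(1/5, 1, 5)`.
#' @param X Optional fixed covariates (intercept added).
#' @return A `gp_fit` with model_tag "RKHS", per-kernel weights in
#'   `kernel_weights`, and the training matrix stored for cross-kernel
#'   prediction.
#' @export
fit_rkhs_multikernel <- function(Z, y, h_set = 0.5 * c(1 / 5, 1, 5),
                                 X = NULL) {
  stopifnot(length(h_set) >= 1, all(h_set > 0))
  Z <- as.matrix(Z)
  K1 <- gaussian_kernel(Z, h_set[1])
  scale <- attr(K1, "distance_scale")
  K_list <- c(list(unclass(K1)),
              lapply(h_set[-1], function(h)
                unclass(gaussian_kernel(Z, h, distance_scale = scale))))
  Xd <- cbind(`(Intercept)` = rep(1, nrow(Z)), X)
  if (length(h_set) == 1) {
    s2 <- NULL
    weights <- 1
    Kbar <- K_list[[1]]
    fit <- fit_gblup(Kbar, y, X = Xd)
    s2b_total <- fit$vc[["sigma2_g"]]
  } else {
    s2 <- reml_multi(K_list, y, X = Xd)
    s2b <- s2[seq_along(h_set)]
    s2b_total <- sum(s2b)
    if (s2b_total <= 1e-10 * stats::var(y)) {
      stop("all kernel variance components collapsed to zero")
    }
    weights <- s2b / s2b_total
    Kbar <- Reduce(`+`, Map(function(K, w) w * K, K_list, weights))
    fit <- fit_gblup(Kbar, y, X = Xd,
                     fixed_ratio = s2b_total / s2[["sigma2_e"]])
  }
  fit$model_tag <- "RKHS"
  fit$h_set <- h_set
  fit$kernel_weights <- unname(weights)
  fit$distance_scale <- scale
  fit$Z_train <- Z
  fit$sigma2_g_bar <- fit$vc[["sigma2_g"]]
  fit$vc_kernels <- s2
  fit$intercept <- fit$beta[1]
  fit$beta_cov <- if (ncol(Xd) > 1) fit$beta[-1] else NULL
  fit
}

cross_kernel_bar <- function(fit, Z_new) {
  if (ncol(Z_new) != ncol(fit$Z_train)) {
    stop("marker-set mismatch: fit has ", ncol(fit$Z_train),
         " markers, Z_new has ", ncol(Z_new))
  }
  d2 <- sq_dist(as.matrix(Z_new), fit$Z_train)
  Kc <- 0
  for (r in seq_along(fit$h_set)) {
    Kc <- Kc + fit$kernel_weights[r] *
      exp(-fit$h_set[r] * d2 / fit$distance_scale)
  }
  Kc
}
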