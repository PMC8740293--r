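#' Principal components of the genotype matrix
#'
#' Singular decomposition of the column-centred genotype matrix. The sign
#' of each component is fixed so its largest-magnitude loading is positive,
#' making repeated runs byte-identical.
#'
#' @param G Complete genotypes ([genotype_matrix()] or matrix).
#' @param n_pc Number of components (default 10; must be below
#'   `min(n, p)`).
#' @return A `structure_info` with `pc_scores` (n x n_pc), `pc_varexp`
#'   (fraction of total variance, non-increasing), and `pc_loadings`.
#' @export
pca_genotypes <- function(G, n_pc = 10) {
  Z <- geno_values(G)
  if (anyNA(Z)) stop("G must be complete (impute first)")
  stopifnot(n_pc >= 1, n_pc < min(dim(Z)))
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  total_var <- sum(Zc^2)
  if (total_var == 0) stop("constant genotype matrix: PCA undefined")
  sv <- svd(Zc)
  flip <- vapply(seq_len(n_pc), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_pc), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_pc)], n_pc), 2, flip, "*")
  loads <- sweep(sv$v[, seq_len(n_pc), drop = FALSE], 2, flip, "*")
  rownames(scores) <- rownames(Z)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  structure(list(pc_scores = scores,
                 pc_varexp = sv$d[seq_len(n_pc)]^2 / total_var,
                 pc_loadings = loads, q_matrix = NULL, labels = NULL),
            class = "structure_info")
}

#' Read an external admixture Q-matrix
#'
#' Ingests the whitespace-delimited per-accession ancestry proportions
#' produced by admixture-model software (one row per accession, one column
#' per cluster) and binds it to the accession order.
#'
#' @param path File path.
#' @param accession_ids Accession IDs in the file's row order.
#' @return A `structure_info` with the validated row-stochastic `q_matrix`
#'   and >60%-ancestry `labels`.
#' @export
read_qmatrix <- function(path, accession_ids) {
  q <- as.matrix(utils::read.table(path, header = FALSE))
  if (nrow(q) != length(accession_ids)) {
    stop("Q-matrix has ", nrow(q), " rows but ", length(accession_ids),
         " accession IDs were supplied")
  }
  bad <- abs(rowSums(q) - 1) > 1e-3
  if (any(bad)) {
    stop("Q-matrix row(s) ", paste(which(bad), collapse = ", "),
         " do not sum to 1 (tolerance 1e-3)")
  }
  rownames(q) <- accession_ids
  colnames(q) <- paste0("SP", seq_len(ncol(q)))
  structure(list(pc_scores = NULL, pc_varexp = NULL, pc_loadings = NULL,
                 q_matrix = q, labels = assign_subpops(q)),
            class = "structure_info")
}

#' Assign subpopulation labels from ancestry proportions
#'
#' An accession is assigned to its maximum-ancestry cluster when that
#' ancestry strictly exceeds `threshold`; otherwise it is "admixed"
#' (membership of exactly the threshold counts as admixed).
#'
#' @param q Row-stochastic ancestry matrix (rows = accessions).
#' @param threshold Ancestry cut-off (default 0.60).
#' @return Named character vector of labels (`SP<k>` or "admixed").
#' @export
assign_subpops <- function(q, threshold = 0.60) {
  q <- as.matrix(q)
  if (is.null(colnames(q))) colnames(q) <- paste0("SP", seq_len(ncol(q)))
  top <- max.col(q, ties.method = "first")
  lab <- ifelse(q[cbind(seq_len(nrow(q)), top)] > threshold,
                colnames(q)[top], "admixed")
  stats::setNames(lab, rownames(q))
}
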