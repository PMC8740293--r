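#' Write / read the numeric genotype matrix as TSV
#'
#' Accessions in rows, markers in columns; marker metadata goes to a
#' sidecar `<path>.meta.tsv`.
#'
#' @param G A [genotype_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  utils::write.table(G$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(G$marker_meta, paste0(path, ".meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(marker_id = colnames(v), stringsAsFactors = FALSE)
  }
  genotype_matrix(v, meta)
}

#' Write / read long-format phenotype records as CSV
#'
#' Columns: accession_id, year_id, trait_name, value.
#'
#' @param records Phenotype records data frame.
#' @param path CSV path.
#' @return `path` (write) or the records data frame (read).
#' @export
write_pheno_csv <- function(records, path) {
  stopifnot(all(c("accession_id", "year_id", "trait_name",
                  "value") %in% names(records)))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno_csv
#' @export
read_pheno_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
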