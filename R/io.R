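# File-format layer: labelled CSV matrices, long phenotype tables,
# sparse-triplet weight exports, JSON run metadata.

#' Read a labelled matrix from CSV
#'
#' Expects a header row of column labels and a first column of row labels.
#' Square matrices (relationship or covariance matrices) are validated to
#' have matching row/column labels when both are present.
#'
#' @param path CSV file path.
#' @param square Require a square matrix (default `FALSE`).
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path, square = FALSE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric entries in ", path)
  if (square && nrow(M) != ncol(M)) {
    stop("matrix in ", path, " is not square (", nrow(M), " x ", ncol(M), ")")
  }
  M
}

#' Write a labelled matrix to CSV
#'
#' @param x Matrix.
#' @param path Output path.
#' @export
write_matrix_csv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- seq_len(ncol(x))
  utils::write.csv(as.data.frame(x), path, row.names = TRUE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' The interchange format for phenotypes is long: one row per record with
#' columns `geno` (genotype id or index), `trait` (trait/environment id or
#' index), `value`.  Row order defines the 1-based record indices used by
#' `trn`/`tst` files.  A wide table (first column genotype id, remaining
#' columns one per trait) is converted on read.
#'
#' @param path CSV file path.
#' @return Tibble with columns `geno`, `trait`, `value`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- tolower(names(df))
  if (all(c("geno", "trait", "value") %in% nms)) {
    names(df) <- nms
    return(tibble::as_tibble(df[, c("geno", "trait", "value")]))
  }
  # wide: genotype id column + one column per trait
  long <- tidyr::pivot_longer(df, -1, names_to = "trait", values_to = "value")
  names(long)[1] <- "geno"
  dplyr::arrange(long, .data$trait, .data$geno)
}

#' Write a long-format phenotype table
#'
#' @param phenotypes Data frame with columns `geno`, `trait`, `value`.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(all(c("geno", "trait", "value") %in% names(phenotypes)))
  utils::write.csv(phenotypes[, c("geno", "trait", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a coefficient or weight path as sparse triplets
#'
#' Writes the non-zero entries of a [solve_elastic_net()] path or [sgp()]
#' weight set as a TSV with columns `lambda_index`, `response_index`,
#' `predictor_index`, `value`, plus a sidecar TSV (`<path>.lambda.tsv`)
#' with the lambda grid.  For `sgp` fits, responses are testing records and
#' predictors are training records (both positional).
#'
#' @param fit A `coef_path` or `sgp` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_coef_triplets <- function(fit, path) {
  trip <- tidy(fit)
  names(trip)[names(trip) == "response"] <- "response_index"
  names(trip)[names(trip) == "predictor"] <- "predictor_index"
  names(trip)[names(trip) == "estimate"] <- "value"
  names(trip)[names(trip) == "weight"] <- "value"
  utils::write.table(trip[, c("lambda_index", "response_index",
                              "predictor_index", "value")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(lambda_index = seq_along(fit$lambda),
                                lambda = fit$lambda),
                     paste0(path, ".lambda.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sparse-triplet coefficient export
#'
#' Reconstructs dense coefficient matrices from the triplet TSV and its
#' lambda sidecar written by [write_coef_triplets()].
#'
#' @param path Triplet TSV path (sidecar `<path>.lambda.tsv` must exist).
#' @param p Number of predictors (rows) of the dense reconstruction.
#' @return List with `lambda` and `beta` (list, per response, of sparse
#'   p x nlambda matrices).
#' @export
read_coef_triplets <- function(path, p) {
  trip <- utils::read.delim(path)
  lam <- utils::read.delim(paste0(path, ".lambda.tsv"))
  beta <- lapply(sort(unique(trip$response_index)), function(r) {
    tr <- trip[trip$response_index == r, ]
    Matrix::sparseMatrix(i = tr$predictor_index, j = tr$lambda_index,
                         x = tr$value, dims = c(p, nrow(lam)))
  })
  list(lambda = lam$lambda, beta = beta)
}

#' Write run metadata as JSON
#'
#' Every pipeline run records enough to reproduce it: input file hashes,
#' seeds, tolerances, the lambda grid, and the package version.
#'
#' @param meta Named list.
#' @param path Output path.
#' @export
write_run_meta <- function(meta, path) {
  meta$package <- "mtsgp"
  meta$version <- as.character(utils::packageVersion("mtsgp"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

file_hashes <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  as.list(tools::md5sum(unlist(paths)))
}
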