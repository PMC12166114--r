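# Genomic relationship matrix.

#' Genomic relationship matrix from marker dosages
#'
#' Builds `K = Z Z' / v` from an n x m marker matrix, where `Z` is the
#' column-centered marker matrix and `v = sum_j var(z_j)` with the
#' method-of-moments variance (denominator n).  This normalization makes
#' the average diagonal of `K` exactly one, so the genetic variance
#' multiplying `K` in a mixed model is on the scale of a single genotype.
#'
#' @param markers Numeric n x m matrix (or data frame) of marker codes,
#'   genotypes in rows.  Row names, if present, label the output.
#' @param center Center each marker column to zero mean (default `TRUE`).
#'   Set to `FALSE` only if `markers` is already centered.
#' @param impute Replace missing entries by their column mean before
#'   centering (default `FALSE`; missing values are otherwise an error).
#' @return Symmetric n x n matrix with genotype labels as dimnames.
#' @examples
#' Z <- matrix(c(1, -1, -1, 1), nrow = 2)  # already centered
#' compute_grm(Z, center = FALSE)
#' @export
compute_grm <- function(markers, center = TRUE, impute = FALSE) {
  Z <- as.matrix(markers)
  storage.mode(Z) <- "double"
  n <- nrow(Z)
  if (n < 2) stop("at least two genotypes are required")
  if (ncol(Z) < 1) stop("at least one marker is required")
  if (anyNA(Z)) {
    if (!impute) stop("missing marker codes; set `impute = TRUE` to use column-mean imputation")
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2]]
    if (anyNA(Z)) stop("markers with all values missing cannot be imputed")
  }
  if (center) Z <- sweep(Z, 2, colMeans(Z), "-")
  v <- sum(colMeans(Z^2)) - sum(colMeans(Z)^2)  # moment variances, denominator n
  if (v <= 0) stop("degenerate input: all markers have zero variance")
  K <- tcrossprod(Z) / v
  ids <- rownames(Z)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(K) <- list(ids, ids)
  K
}
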