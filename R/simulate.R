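# Synthetic-data generators: everything the test suite and examples need,
# with no external downloads.  All generators are pure functions of their
# arguments plus `seed`.

#' Simulate a sparse-effect regression problem
#'
#' Generates a standardized Gaussian predictor matrix with a sparse,
#' Gamma-distributed effect vector: exactly `round(p * prop_nonzero)`
#' effects are non-zero, drawn from Gamma(`effect_shape`, `effect_rate`)
#' (all positive by default; `sign_flip` randomizes signs for
#' symmetric-effect tests).  The response is `scale(X %*% b + e)` with
#' `e ~ N(0, (noise_mult * sd(X %*% b))^2)`.
#'
#' @param n,p Sample size and number of predictors (defaults 3000, 500).
#' @param prop_nonzero Fraction of non-zero effects in (0, 1\] (default 0.1).
#' @param effect_shape,effect_rate Gamma-law parameters (defaults 4, 4).
#' @param noise_mult Error standard deviation as a multiple of the signal
#'   standard deviation (default 3; 0 gives a noiseless response).
#' @param sign_flip Randomly negate half the effects (default `FALSE`).
#' @param seed Optional RNG seed.
#' @return List with `X` (n x p, standardized), `y` (scaled response),
#'   `beta` (true effects), `signal`.
#' @export
simulate_regression <- function(n = 3000, p = 500, prop_nonzero = 0.1,
                                effect_shape = 4, effect_rate = 4,
                                noise_mult = 3, sign_flip = FALSE,
                                seed = NULL) {
  stopifnot(n >= 2, p >= 1, prop_nonzero > 0, prop_nonzero <= 1,
            noise_mult >= 0)
  if (!is.null(seed)) set.seed(seed)
  nz <- max(1L, round(p * prop_nonzero))
  b <- numeric(p)
  b[sample.int(p, nz)] <- rgamma(nz, effect_shape, effect_rate)
  if (sign_flip) {
    pick <- b != 0
    b[pick] <- b[pick] * sample(c(-1, 1), sum(pick), replace = TRUE)
  }
  X <- scale(matrix(rnorm(n * p), ncol = p))
  signal <- as.numeric(X %*% b)
  err_sd <- noise_mult * sd(signal)
  e <- if (err_sd > 0) rnorm(n, sd = err_sd) else numeric(n)
  y <- as.numeric(scale(signal + e))
  list(X = X, y = y, beta = b, signal = signal)
}

sqrt_psd <- function(M, name = "matrix") {
  eg <- eigen(M, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    stop("`", name, "` is not positive semidefinite")
  }
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate multi-trait genomic data
#'
#' Draws biallelic marker dosages (doubled-haploid style codes in {0, 2}
#' with allele frequencies uniform on `maf`), builds the genomic
#' relationship matrix with [compute_grm()], and generates stacked
#' phenotypes under the multi-trait model: genetic values with covariance
#' `Omega %x% K` (via matrix square roots of `Omega` and `K`) and
#' residuals with covariance `R %x% I`, so `y = g + e` on a complete
#' n x q (genotype, trait) record grid.  `missing_rate` optionally marks a
#' random fraction of records as unobserved (a deletion mask for
#' incomplete-data tests; phenotype values are set `NA`).
#'
#' @param n,m Number of genotypes and markers.
#' @param Omega,R q x q genetic and error covariance matrices (scalars for
#'   q = 1); both must be PSD.
#' @param maf Allele-frequency range (default `c(0.1, 0.5)`).
#' @param missing_rate Fraction of records masked as missing (default 0).
#' @param seed Optional RNG seed.
#' @return List with `markers` (n x m), `K`, `phenotypes` (long tibble:
#'   `geno`, `trait`, `value`, trait-major record order), `y` (stacked
#'   vector with `NA` at masked records), `g` (true genetic values,
#'   stacked), `index` (complete [stacked_index()] with observed records
#'   as `trn`), `Omega`, `R`.
#' @export
simulate_multitrait <- function(n, m, Omega, R, maf = c(0.1, 0.5),
                                missing_rate = 0, seed = NULL) {
  as_psd <- function(M, name) {
    if (length(M) == 1 && !is.matrix(M)) M <- matrix(as.numeric(M), 1, 1)
    M <- as.matrix(M)
    if (nrow(M) != ncol(M) ||
        max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
      stop("`", name, "` must be a symmetric square matrix")
    }
    M
  }
  Omega <- as_psd(Omega, "Omega")  # PSD enforced by sqrt_psd below
  R <- as_psd(R, "R")
  if (nrow(R) != nrow(Omega)) stop("`Omega` and `R` dimensions differ")
  q <- nrow(Omega)
  stopifnot(n >= 2, m >= 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)

  p_allele <- runif(m, maf[1], maf[2])
  markers <- vapply(p_allele, function(pa) 2 * rbinom(n, 1, pa), numeric(n))
  rownames(markers) <- as.character(seq_len(n))
  K <- compute_grm(markers)

  Ksq <- sqrt_psd(K, "K")
  Osq <- sqrt_psd(Omega, "Omega")
  Rsq <- sqrt_psd(R, "R")
  Gmat <- Ksq %*% matrix(rnorm(n * q), n, q) %*% Osq  # cov = Omega x K
  Emat <- matrix(rnorm(n * q), n, q) %*% Rsq          # cov = R x I
  g <- as.numeric(Gmat)
  y <- g + as.numeric(Emat)

  ID_geno <- rep(seq_len(n), times = q)
  ID_trait <- rep(seq_len(q), each = n)
  obs <- seq_len(n * q)
  if (missing_rate > 0) {
    drop <- sample(n * q, round(missing_rate * n * q))
    y[drop] <- NA_real_
    obs <- setdiff(obs, drop)
  }
  idx <- stacked_index(ID_geno, ID_trait, trn = obs)
  phen <- tibble::tibble(geno = ID_geno, trait = ID_trait, value = y)
  list(markers = markers, K = K, phenotypes = phen, y = y, g = g,
       index = idx, Omega = Omega, R = R)
}

#' Simulate a family-structured, sparse-signal genomic dataset
#'
#' Emulates the regime where only close relatives carry predictive signal:
#' genotypes come in full-sib-like families (each family derives from one
#' founder genotype, with a fraction `mutation_rate` of marker codes
#' redrawn per individual), and genetic values are dominated by a
#' family-level effect (`family_prop` of the genetic variance) plus a small
#' individual deviation.  The marker-based GRM then carries sampling noise
#' between unrelated families, so prediction equations that select the few
#' truly informative (within-family) training records can outperform ones
#' that weight every record.
#'
#' @param n_families,family_size Family structure (defaults 30 x 5).
#' @param m Number of markers (default 200; few relative to n, so the GRM
#'   is noisy between families).
#' @param h2 Narrow-sense heritability of the phenotype (default 0.6).
#' @param family_prop Fraction of genetic variance at the family level
#'   (default 0.9).
#' @param mutation_rate Per-marker probability that an individual's code is
#'   redrawn from the population frequency (default 0.15).
#' @param maf Allele-frequency range for founder markers.
#' @param seed Optional RNG seed.
#' @return List with `markers`, `K`, `y`, `g`, `family` (family id per
#'   genotype), `index` (single-trait [stacked_index()], all records
#'   training), `h2`.
#' @export
simulate_sparse_signal <- function(n_families = 30, family_size = 5, m = 200,
                                   h2 = 0.6, family_prop = 0.9,
                                   mutation_rate = 0.15, maf = c(0.1, 0.5),
                                   seed = NULL) {
  stopifnot(n_families >= 2, family_size >= 2, m >= 1,
            h2 > 0, h2 < 1, family_prop >= 0, family_prop <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_families * family_size
  family <- rep(seq_len(n_families), each = family_size)

  p_allele <- runif(m, maf[1], maf[2])
  founders <- vapply(p_allele, function(pa) 2 * rbinom(n_families, 1, pa),
                     numeric(n_families))
  markers <- founders[family, , drop = FALSE]
  for (j in seq_len(m)) {
    flip <- runif(n) < mutation_rate
    if (any(flip)) markers[flip, j] <- 2 * rbinom(sum(flip), 1, p_allele[j])
  }
  rownames(markers) <- as.character(seq_len(n))
  K <- compute_grm(markers)

  f <- rnorm(n_families)
  g <- sqrt(family_prop) * f[family] + sqrt(1 - family_prop) * rnorm(n)
  e <- rnorm(n, sd = sqrt(var(g) * (1 - h2) / h2))
  y <- g + e

  list(markers = markers, K = K, y = y, g = g, family = family,
       index = stacked_index(seq_len(n), rep(1L, n), trn = seq_len(n)),
       h2 = h2)
}
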