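# Shared fixture builders and independent oracles.

# Random positive-definite covariance-like matrix (crossprod of a tall
# Gaussian matrix is PD almost surely).
rand_pd_sigma <- function(p, n = p + 10) {
  A <- matrix(rnorm(n * p), n, p)
  crossprod(A) / n
}

# Independent numeric minimizer of the Elastic-Net objective
#   0.5 b'S b - b'g + lam * (alpha |b|_1 + 0.5 (1-alpha) |b|^2)
# via Nelder-Mead/BFGS on a smoothed-free exact objective using optim from
# many starts; used only on tiny problems.
en_objective <- function(b, S, gam, lam, alpha) {
  0.5 * sum(b * (S %*% b)) - sum(b * gam) +
    lam * (alpha * sum(abs(b)) + 0.5 * (1 - alpha) * sum(b^2))
}

en_brute_min <- function(S, gam, lam, alpha, starts = 8) {
  p <- length(gam)
  best <- NULL
  for (s in seq_len(starts)) {
    b0 <- if (s == 1) numeric(p) else rnorm(p, sd = 0.5)
    fit <- optim(b0, en_objective, S = S, gam = gam, lam = lam, alpha = alpha,
                 method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

# Fully materialized stacked covariance (Omega x K) + (R x I): the
# brute-force oracle for build_P/build_G subsetting.  Record order is
# trait-major: genotype 1..n of trait 1, then trait 2, ...
kron_P_full <- function(K, Omega, R) {
  n <- nrow(K)
  kronecker(Omega, K) + kronecker(R, diag(n))
}

kron_G_full <- function(K, Omega) {
  kronecker(Omega, K)
}

# Record index (trait-major) of genotype g, trait t with n genotypes.
rec_id <- function(g, t, n) (t - 1L) * n + g

# Small single-trait genomic fixture with a structured GRM (families give
# the likelihood surface real curvature at modest n).
family_fixture <- function(seed, n_families = 20, family_size = 5, m = 150,
                           h2 = 0.5) {
  simulate_sparse_signal(n_families = n_families, family_size = family_size,
                         m = m, h2 = h2, seed = seed)
}
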