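test_that("stacked_index validates its invariants", {
  idx <- stacked_index(rep(1:3, 2), rep(1:2, each = 3), trn = 1:4, tst = 5:6)
  expect_s3_class(idx, "stacked_index")
  expect_equal(nrow(idx$records), 6)
  expect_error(stacked_index(rep(1:3, 2), rep(1:2, each = 3),
                             trn = 1:4, tst = 4:6), "disjoint")
  expect_error(stacked_index(c(1, 1), c(1, 1), trn = 1:2), "duplicate")
  expect_error(stacked_index(1:4, rep(1, 4), trn = 1:3, tst = 9), "range")
})

test_that("build_P / build_G match the hand-computed Kronecker entries", {
  K <- diag(2)
  Omega <- matrix(c(1, 0.5, 0.5, 1), 2)
  R <- diag(2)
  rows <- data.frame(geno = c(1, 1, 2), trait = c(1, 2, 1))
  P <- build_P(K, Omega, R, rows)
  # (geno1,trait1) x (geno1,trait2): Omega[1,2]*K[1,1] + R[1,2]*1 = 0.5
  expect_equal(P[1, 2], 0.5)
  # (geno1,trait1) x (geno2,trait1): Omega[1,1]*K[1,2] = 0
  expect_equal(P[1, 3], 0)
  expect_equal(diag(P), rep(2, 3))  # Omega_kk*K_gg + R_kk

  # q = 1 reduces to varU*K + varE*I
  set.seed(10)
  Z <- matrix(sample(0:2, 8 * 30, replace = TRUE), 8, 30)
  K8 <- compute_grm(Z)
  rows1 <- data.frame(geno = 1:8, trait = rep(1L, 8))
  expect_equal(build_P(K8, 0.4, 0.6, rows1), 0.4 * K8 + 0.6 * diag(8),
               ignore_attr = TRUE)
  expect_equal(build_G(K8, 0.4, rows1, rows1[1:3, ]), 0.4 * K8[, 1:3],
               ignore_attr = TRUE)

  # diagonal Omega zeroes all cross-trait entries of G
  rows2 <- data.frame(geno = c(1, 2), trait = c(1, 2))
  G <- build_G(K8, diag(c(0.3, 0.7)), rows2, rows2)
  expect_equal(G[1, 2], 0)
  expect_equal(G[2, 1], 0)
})

test_that("build_P / build_G equal submatrices of the materialized Kronecker", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:10, 1); q <- sample(2:3, 1)
    Z <- matrix(sample(0:2, n * 40, replace = TRUE), n, 40)
    K <- compute_grm(Z)
    A <- matrix(rnorm(q * q), q); Omega <- crossprod(A) / q + 0.1 * diag(q)
    B <- matrix(rnorm(q * q), q); R <- crossprod(B) / q + 0.1 * diag(q)
    Pfull <- kron_P_full(K, Omega, R)
    Gfull <- kron_G_full(K, Omega)
    # random incomplete-data record subsets
    nrec <- n * q
    rows <- sort(sample(nrec, sample(2:(nrec - 2), 1)))
    cols <- sort(sample(nrec, sample(2:(nrec - 2), 1)))
    rd <- data.frame(geno = (rows - 1) %% n + 1, trait = (rows - 1) %/% n + 1)
    cd <- data.frame(geno = (cols - 1) %% n + 1, trait = (cols - 1) %/% n + 1)
    expect_equal(build_P(K, Omega, R, rd, cd), Pfull[rows, cols, drop = FALSE],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(build_G(K, Omega, rd, cd), Gfull[rows, cols, drop = FALSE],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pure subsetting: dropping a training record leaves other blocks unchanged", {
  set.seed(12)
  n <- 8; q <- 2
  K <- compute_grm(matrix(sample(0:2, n * 30, replace = TRUE), n, 30))
  Omega <- matrix(c(0.5, 0.2, 0.2, 0.8), 2); R <- diag(0.3, 2)
  recs <- data.frame(geno = rep(1:n, q), trait = rep(1:q, each = n))
  trn <- c(1:6, 9:14)
  P <- build_P(K, Omega, R, recs[trn, ])
  keep <- trn[-3]
  expect_equal(build_P(K, Omega, R, recs[keep, ]), P[-3, -3])
})

test_that("single-trait SGP at lambda = 0 reproduces fitBLUP's GBLUP", {
  sim <- family_fixture(seed = 81)
  n <- length(sim$y)
  set.seed(82)
  tst <- sort(sample(n, 20)); trn <- setdiff(seq_len(n), tst)
  fb <- fit_blup(sim$y, sim$K, trn = trn)
  # variances estimated internally (same method), lambda = 0 direct solve
  fm <- sgp(y = sim$y, K = sim$K, trn = trn, tst = tst, lambda = c(1, 0))
  expect_lt(max(abs(fm$yHat[, 2] - fb$yHat[tst])), 1e-6)
  # and with the variances passed explicitly
  fm2 <- sgp(y = sim$y, K = sim$K, varU = fb$varU, varE = fb$varE,
             trn = trn, tst = tst, lambda = c(1, 0))
  expect_lt(max(abs(fm2$yHat[, 2] - fb$yHat[tst])), 1e-6)
})

test_that("multi-trait SGP at lambda = 0 equals the direct multivariate solve", {
  set.seed(83)
  Omega <- matrix(c(0.6, 0.3, 0.1, 0.3, 0.5, 0.2, 0.1, 0.2, 0.7), 3)
  sim <- simulate_multitrait(n = 60, m = 120, Omega = Omega, R = diag(0.4, 3),
                             seed = 84)
  part <- cv2_partition(n = 60, q = 3, n0 = 20, seed = 85)
  fm <- sgp(y = sim$y, K = sim$K, varU = Omega, varE = diag(0.4, 3),
            index = part, lambda = c(1, 0))
  Pfull <- kron_P_full(sim$K, Omega, diag(0.4, 3))
  Gfull <- kron_G_full(sim$K, Omega)
  ghat <- crossprod(Gfull[part$trn, part$tst],
                    solve(Pfull[part$trn, part$trn], sim$y[part$trn]))
  expect_lt(max(abs(fm$yHat[, 2] - ghat)), 1e-6)
  # weights at the top of a full default path are all zero
  fm_path <- sgp(y = sim$y, K = sim$K, varU = Omega, varE = diag(0.4, 3),
                 index = part, nlambda = 20)
  expect_equal(fm_path$nsup[1], 0)
  expect_true(all(fm_path$yHat[, 1] == 0))
})

test_that("diagonal Omega and R decouple MT-SGP into per-trait ST-SGP", {
  q <- 3
  Omega <- diag(c(0.5, 0.7, 0.3)); R <- diag(c(0.5, 0.3, 0.7))
  sim <- simulate_multitrait(n = 50, m = 100, Omega = Omega, R = R, seed = 86)
  part <- cv2_partition(n = 50, q = q, n0 = 15, seed = 87)
  fm <- sgp(y = sim$y, K = sim$K, varU = Omega, varE = R, index = part,
            nlambda = 15)
  for (tr in 1:q) {
    trn_t <- part$trn[part$records$trait[part$trn] == tr]
    tst_t <- part$tst[part$records$trait[part$tst] == tr]
    if (!length(tst_t)) next
    st <- sgp(y = sim$y, K = sim$K,
              varU = Omega[tr, tr], varE = R[tr, tr],
              trn = trn_t, tst = tst_t,
              ID_geno = part$records$geno, ID_trait = rep(1L, nrow(part$records)),
              lambda = fm$lambda)
    rows_mt <- match(tst_t, part$tst)
    cols_mt <- match(trn_t, part$trn)
    for (l in seq_along(fm$lambda)) {
      W_mt <- as.matrix(fm$weights[[l]])[rows_mt, cols_mt, drop = FALSE]
      W_st <- as.matrix(st$weights[[l]])
      expect_lt(max(abs(W_mt - W_st)), 1e-8)
      # cross-trait weights are exactly zero in the decoupled system
      expect_equal(sum(abs(as.matrix(fm$weights[[l]])[rows_mt, -cols_mt])), 0)
    }
  }
})

test_that("relabelling genotypes permutes predictions identically", {
  sim <- family_fixture(seed = 88, n_families = 10, family_size = 4)
  n <- length(sim$y)
  set.seed(89)
  tst <- sort(sample(n, 8)); trn <- setdiff(seq_len(n), tst)
  fm <- sgp(y = sim$y, K = sim$K, varU = 0.4, varE = 0.6, trn = trn,
            tst = tst, nlambda = 10)
  pi <- sample(n)  # new genotype order; record r now maps to genotype pos[r]
  pos <- match(seq_len(n), pi)
  fm_p <- sgp(y = sim$y, K = sim$K[pi, pi], varU = 0.4, varE = 0.6,
              trn = trn, tst = tst, ID_geno = pos,
              ID_trait = rep(1L, n), nlambda = 10)
  expect_equal(fm$lambda, fm_p$lambda)
  expect_equal(fm$yHat, fm_p$yHat, tolerance = 1e-10)
})

test_that("nsup endpoints and prediction mechanics behave as documented", {
  sim <- family_fixture(seed = 90, n_families = 10, family_size = 4)
  n <- length(sim$y)
  tst <- 1:6; trn <- 7:n
  lmax <- max(abs(build_G(sim$K, 0.4,
                          data.frame(geno = trn, trait = 1),
                          data.frame(geno = tst, trait = 1))))
  fm <- sgp(y = sim$y, K = sim$K, varU = 0.4, varE = 0.6, trn = trn,
            tst = tst, lambda = c(lmax * 1.001, lmax * 0.5, 0))
  expect_equal(fm$nsup[1], 0)
  expect_equal(fm$nsup[3], length(trn))  # lambda = 0 is dense
  # predictions at lambda >= lambda_max equal the intercept (0 on centered scale)
  expect_equal(fm$yHat[, 1], rep(fm$intercept, length(tst)),
               ignore_attr = TRUE)

  # predict_from_weights: raw weighted sums
  pw <- predict_from_weights(fm, sim$y[trn])
  expect_equal(pw[, 1], rep(0, length(tst)), ignore_attr = TRUE)
  W2 <- as.matrix(fm$weights[[2]])
  expect_equal(pw[, 2], as.numeric(W2 %*% sim$y[trn]), ignore_attr = TRUE)
  expect_error(predict_from_weights(fm, sim$y[trn][-1]), "length")
})

test_that("sgp validates inputs", {
  sim <- family_fixture(seed = 91, n_families = 8, family_size = 4)
  n <- length(sim$y)
  expect_error(sgp(y = sim$y, K = sim$K, varU = 0.4, varE = 0.6,
                   trn = integer(0), tst = 1:3), "non-empty")
  expect_error(sgp(y = sim$y, K = sim$K, varU = 0.4, varE = 0.6,
                   trn = 1:10, tst = 10:12), "disjoint")
  expect_error(sgp(y = sim$y, K = sim$K, trn = 1:20, tst = 21:25,
                   ID_geno = seq_len(n), ID_trait = rep(1:2, length.out = n)),
               "q > 1")
  expect_error(sgp(y = sim$y, K = sim$K, varU = 0.4, varE = 0.6,
                   trn = 1:20, tst = 21:25, ID_geno = c(seq_len(n - 1), n + 5)),
               "beyond")
})

test_that("solve_ssi recovers the Smith-Hazel index at lambda 0 and thresholds", {
  set.seed(92)
  Px <- rand_pd_sigma(4)
  Gxy <- rnorm(4)
  fit <- solve_ssi(Px, Gxy, lambda = 0, tol = 1e-12, maxiter = 1e5)
  expect_equal(as.numeric(coef(fit)), as.numeric(solve(Px, Gxy)),
               tolerance = 1e-8)

  fit2 <- solve_ssi(diag(3), c(0.3, 0, 0.1), lambda = 0.2, tol = 1e-12)
  expect_equal(as.numeric(coef(fit2)), c(0.1, 0, 0))

  # index variance decreases as lambda increases (grid is decreasing, so
  # variance is non-decreasing along the path columns)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4) %*% chol(Px)
  path <- solve_ssi(Px, Gxy, nlambda = 25)
  v <- apply(predict(path, X), 2, var)
  expect_true(all(diff(v) > -1e-10))
})
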