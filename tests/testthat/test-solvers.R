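test_that("soft_threshold shrinks toward zero and preserves sign", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(c(0.2, -0.2, 0), 0.2), c(0, 0, 0))
  expect_error(soft_threshold(1, -0.1))
})

test_that("lambda_max is the KKT threshold for the all-zero solution", {
  expect_equal(lambda_max(c(1, 0.5), alpha = 1), 1)
  expect_equal(lambda_max(c(-2, 1), alpha = 0.5), 4)
  expect_error(lambda_max(c(0, 0)), "degenerate")
  # alpha = 0 uses the documented floor, for grid sizing only
  expect_equal(lambda_max(c(1, 0.5), alpha = 0, alpha_floor = 1e-3), 1000)

  # at lambda = lambda_max the solver returns exactly zero; just below, not
  set.seed(42)
  for (i in 1:5) {
    p <- sample(3:12, 1)
    S <- rand_pd_sigma(p)
    g <- rnorm(p)
    lm <- lambda_max(g, alpha = 1)
    fit <- solve_elastic_net(S, g, alpha = 1, lambda = c(lm * 1.0001, lm * 0.95),
                             tol = 1e-10)
    expect_true(all(coef(fit, 1) == 0))
    expect_gt(max(abs(coef(fit, 2))), 0)
  }
})

test_that("lambda_grid is log-spaced, anchored at lambda_max", {
  g <- lambda_grid(1, nlambda = 3, min_ratio = 0.01)
  expect_equal(g, c(1, 0.1, 0.01))
  expect_length(lambda_grid(2.5), 100)
  expect_identical(lambda_grid(3.7, 10, 0.5)[1], 3.7)
  expect_true(all(diff(lambda_grid(1)) < 0))
  expect_error(lambda_grid(1, nlambda = 1))
  expect_error(lambda_grid(1, min_ratio = 1.5))
})

test_that("coordinate descent matches closed forms on tiny instances", {
  # unpenalized solution is the direct linear solve
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- solve_elastic_net(S, c(1, 1), alpha = 1, lambda = 0, tol = 1e-12,
                           maxiter = 1e5)
  expect_equal(as.numeric(coef(fit)), c(2 / 3, 2 / 3), tolerance = 1e-8)

  # orthonormal Sigma: solution is the soft-thresholded Gamma
  fit2 <- solve_elastic_net(diag(2), c(1, 0.5), alpha = 1, lambda = 0.25,
                            tol = 1e-12)
  expect_equal(as.numeric(coef(fit2)), c(0.75, 0.25), tolerance = 1e-8)

  # cross-check against an independent numeric minimizer of the objective
  set.seed(7)
  S3 <- rand_pd_sigma(3)
  g3 <- rnorm(3)
  for (al in c(0.4, 1)) {
    b_cd <- as.numeric(coef(solve_elastic_net(S3, g3, alpha = al, lambda = 0.15,
                                              tol = 1e-12, maxiter = 1e5)))
    b_or <- en_brute_min(S3, g3, 0.15, al)
    expect_equal(b_cd, b_or, tolerance = 1e-3)
  }
})

test_that("ridge closed form and KKT certificate hold on random instances", {
  set.seed(101)
  for (i in 1:25) {
    p <- sample(2:20, 1)
    S <- rand_pd_sigma(p)
    g <- rnorm(p)
    lam <- sort(c(exp(runif(4, -4, 0)) * max(abs(g))), decreasing = TRUE)

    rid <- solve_elastic_net(S, g, alpha = 0, lambda = lam, tol = 1e-11,
                             maxiter = 1e5)
    for (l in seq_along(lam)) {
      expect_equal(as.numeric(coef(rid, l)),
                   as.numeric(solve(S + lam[l] * diag(p), g)),
                   tolerance = 1e-7)
    }

    al <- runif(1, 0.1, 1)
    en <- solve_elastic_net(S, g, alpha = al, lambda = lam, tol = 1e-11,
                            maxiter = 1e5)
    expect_lt(max(kkt_violation(en, S, g)), 1e-7)
  }
})

test_that("warm-started and cold-started paths agree", {
  set.seed(11)
  S <- rand_pd_sigma(15)
  g <- rnorm(15)
  tol <- 1e-8
  warm <- solve_elastic_net(S, g, alpha = 0.9, tol = tol, maxiter = 1e5)
  cold <- solve_elastic_net(S, g, alpha = 0.9, lambda = warm$lambda,
                            tol = tol, maxiter = 1e5, warm_start = FALSE)
  expect_lt(max(abs(as.matrix(warm$beta[[1]]) - as.matrix(cold$beta[[1]]))),
            10 * tol)
})

test_that("multi-response Gamma is solved per column with a shared grid", {
  set.seed(21)
  S <- rand_pd_sigma(8)
  G <- matrix(rnorm(8 * 3), 8, 3)
  fit <- solve_elastic_net(S, G, alpha = 1, nlambda = 12)
  expect_length(fit$beta, 3)
  expect_equal(dim(fit$iterations), c(12L, 3L))
  # equals independent single-column solves on the same grid
  for (j in 1:3) {
    one <- solve_elastic_net(S, G[, j], alpha = 1, lambda = fit$lambda)
    expect_equal(as.matrix(fit$beta[[j]]), as.matrix(one$beta[[1]]))
  }
  # sparse storage round-trips losslessly
  expect_identical(as.matrix(as(as.matrix(fit$beta[[1]]), "CsparseMatrix")),
                   as.matrix(fit$beta[[1]]))
})

test_that("invalid sufficient statistics are rejected; non-convergence is flagged", {
  S <- matrix(c(1, 0.9, 0.1, 1), 2)  # asymmetric
  expect_error(solve_elastic_net(S, c(1, 1)), "symmetric")
  expect_error(solve_elastic_net(diag(2), c(1, 2, 3)), "rows")
  expect_error(solve_elastic_net(diag(c(1, -1)), c(1, 1)), "diagonal")
  set.seed(5)
  Sp <- rand_pd_sigma(10)
  expect_warning(
    fit <- solve_elastic_net(Sp, rnorm(10), alpha = 1, tol = 1e-14,
                             maxiter = 2),
    "converge")
  expect_false(all(fit$converged))
})

test_that("solutions agree with glmnet on raw-data sufficient statistics", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  n <- 300; p <- 25
  X <- scale(matrix(rnorm(n * p), n, p))
  b <- c(rep(1.5, 4), rep(0, p - 4))
  y <- as.numeric(X %*% b + rnorm(n, sd = 2))
  S <- crossprod(X) / n
  g <- as.numeric(crossprod(X, y)) / n
  lam <- lambda_grid(lambda_max(g, 1), nlambda = 20, min_ratio = 0.01)
  ours <- solve_elastic_net(S, g, alpha = 1, lambda = lam, tol = 1e-10,
                            maxiter = 1e5)
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(as.matrix(ours$beta[[1]]) - as.matrix(gn$beta))), 1e-4)
})

test_that("LARS recovers the exact LASSO path", {
  # hand-checkable orthonormal case
  lp <- lars_path(diag(2), c(1, 0.5))
  expect_equal(lp$lambda, c(1, 0.5, 0))
  expect_equal(as.matrix(lp$beta[[1]])[, 2], c(0.5, 0))
  expect_equal(as.matrix(lp$beta[[1]])[, 3], c(1, 0.5))

  set.seed(55)
  for (i in 1:10) {
    p <- sample(2:15, 1)
    S <- rand_pd_sigma(p)
    g <- rnorm(p)
    lp <- lars_path(S, g)
    # last path point is the unpenalized solution
    expect_equal(as.matrix(lp$beta[[1]])[, length(lp$lambda)],
                 as.numeric(solve(S, g)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # every breakpoint satisfies the LASSO KKT conditions
    expect_lt(max(kkt_violation(lp, S, g)), 1e-8)
    # coordinate descent agrees at interior breakpoints
    interior <- lp$lambda[lp$lambda > 0]
    tol <- 1e-9
    cd <- solve_elastic_net(S, g, alpha = 1, lambda = interior, tol = tol,
                            maxiter = 1e5)
    expect_lt(max(abs(as.matrix(lp$beta[[1]])[, seq_along(interior)] -
                        as.matrix(cd$beta[[1]]))), 10 * tol)
  }
})

test_that("LARS rejects duplicate predictors and multi-column Gamma returns a list", {
  S <- matrix(1, 2, 2)  # perfectly collinear predictors
  expect_error(lars_path(S, c(1, 1)), "singular|duplicate")
  set.seed(9)
  Sp <- rand_pd_sigma(5)
  res <- lars_path(Sp, matrix(rnorm(10), 5, 2))
  expect_true(is.list(res) && length(res) == 2)
  expect_s3_class(res[[1]], "coef_path")
})
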