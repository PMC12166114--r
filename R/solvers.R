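# Core penalized solvers operating on sufficient statistics (Sigma, Gamma).

#' Soft-thresholding operator
#'
#' Computes `sign(z) * max(|z| - t, 0)`, the proximal operator of the L1
#' penalty used inside coordinate descent.
#'
#' @param z Numeric vector.
#' @param t Non-negative threshold (scalar or vector recycled against `z`).
#' @return Numeric vector of the same length as `z`.
#' @examples
#' soft_threshold(3, 1)
#' soft_threshold(c(-0.5, -3), 1)
#' @export
soft_threshold <- function(z, t) {
  stopifnot(is.numeric(z), is.numeric(t), all(t >= 0))
  sign(z) * pmax(abs(z) - t, 0)
}

#' Smallest penalty giving an all-zero solution
#'
#' For the objective `0.5 b'Sigma b - b'Gamma + lambda * F(b)` with mixing
#' parameter `alpha`, the zero vector satisfies the KKT conditions iff
#' `max_j |Gamma_j| <= lambda * alpha`, so the smallest such lambda is
#' `max_j |Gamma_j| / alpha`.  For a pure ridge penalty (`alpha = 0`) no
#' finite lambda zeroes the solution; a small floor (`alpha_floor`) is used
#' instead, only to size the grid.
#'
#' @param gamma Numeric vector (one column of Gamma); must not be all zero.
#' @param alpha L1/L2 mixing parameter in \[0, 1\].
#' @param alpha_floor Positive constant replacing `alpha` when `alpha = 0`.
#' @return Positive scalar.
#' @export
lambda_max <- function(gamma, alpha = 1, alpha_floor = 1e-3) {
  stopifnot(is.numeric(gamma), length(gamma) >= 1,
            is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  g <- max(abs(gamma))
  if (g == 0) {
    stop("degenerate input: `gamma` is all zero, lambda_max is undefined")
  }
  g / max(alpha, alpha_floor)
}

#' Log-spaced penalty grid
#'
#' Returns `nlambda` values log-equally spaced from `lam_max` down to
#' `lam_max * min_ratio` (glmnet-style spacing).  The first element equals
#' `lam_max` exactly; `lambda = 0` is never appended (request the
#' unpenalized solution explicitly).
#'
#' @param lam_max Largest penalty value (positive).
#' @param nlambda Grid length, at least 2 (default 100).
#' @param min_ratio Ratio of the smallest to the largest value, in (0, 1).
#' @return Strictly decreasing numeric vector of length `nlambda`.
#' @export
lambda_grid <- function(lam_max, nlambda = 100, min_ratio = 1e-4) {
  stopifnot(is.numeric(lam_max), length(lam_max) == 1, lam_max > 0)
  if (!is.numeric(nlambda) || length(nlambda) != 1 || nlambda < 2 ||
      nlambda != round(nlambda)) {
    stop("`nlambda` must be an integer >= 2")
  }
  if (!is.numeric(min_ratio) || min_ratio <= 0 || min_ratio >= 1) {
    stop("`min_ratio` must lie in (0, 1)")
  }
  out <- exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = nlambda))
  out[1] <- lam_max
  out
}

check_sufficient_stats <- function(Sigma, Gamma, tol = 1e-8) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma)) stop("`Sigma` must be square")
  sc <- max(abs(Sigma))
  if (sc > 0 && max(abs(Sigma - t(Sigma))) > tol * sc) {
    stop("`Sigma` must be symmetric")
  }
  if (any(diag(Sigma) <= 0)) stop("`Sigma` must have strictly positive diagonal")
  Gamma <- as.matrix(Gamma)
  if (nrow(Gamma) != nrow(Sigma)) {
    stop("`Gamma` must have as many rows as `Sigma` (",
         nrow(Sigma), "), got ", nrow(Gamma))
  }
  list(Sigma = Sigma, Gamma = Gamma)
}

#' Elastic-Net solutions from sufficient statistics
#'
#' Solves, by covariance-update coordinate descent, the penalized quadratic
#' problem
#' \deqn{\hat\beta = \arg\min_\beta \tfrac12 \beta'\Sigma\beta - \beta'\Gamma
#'   + \lambda\left[\alpha\sum_j|\beta_j| +
#'   \tfrac{1-\alpha}{2}\sum_j\beta_j^2\right]}
#' for every column of `Gamma` over a decreasing `lambda` grid.  `Sigma` and
#' `Gamma` are the sufficient statistics of a linear model (predictor
#' (co)variance and predictor-response covariance); the solver never
#' rescales them, so callers own the scaling.  Solutions are warm-started
#' along the grid; convergence at each `lambda` is declared when the largest
#' absolute coefficient change in a full sweep falls below `tol`.
#'
#' When `lambda` is `NULL` the grid is generated with [lambda_max()] (the
#' maximum over response columns) and [lambda_grid()].
#'
#' @param Sigma Symmetric p x p matrix with positive diagonal.
#' @param Gamma p-vector or p x m matrix (m response columns).
#' @param alpha L1/L2 mixing parameter in \[0, 1\] (1 = LASSO, 0 = ridge).
#' @param lambda Optional decreasing vector of non-negative penalties.
#' @param nlambda,min_ratio Grid size and span used when `lambda` is `NULL`.
#' @param tol Convergence tolerance on the coefficient sup-norm change.
#' @param maxiter Maximum number of sweeps per `lambda` value;
#'   non-convergence is flagged per `lambda`, not fatal.
#' @param warm_start Warm-start along the grid (`TRUE`) or solve each
#'   `lambda` from the zero vector (`FALSE`); solutions agree to solver
#'   tolerance either way.
#' @return An object of class `coef_path`: a list with elements `lambda`,
#'   `beta` (list of sparse p x nlambda [Matrix::dgCMatrix] matrices, one
#'   per response column), `iterations`, `converged`, `alpha`, `tol`.
#' @seealso [lars_path()] for the exact LASSO path, [tidy.coef_path()].
#' @examples
#' Sigma <- diag(2)
#' fit <- solve_elastic_net(Sigma, c(1, 0.5), alpha = 1, lambda = c(0.25))
#' coef(fit)  # soft_threshold(Gamma, 0.25) for orthonormal Sigma
#' @export
solve_elastic_net <- function(Sigma, Gamma, alpha = 1, lambda = NULL,
                              nlambda = 100, min_ratio = 1e-4,
                              tol = 1e-4, maxiter = 1000, warm_start = TRUE) {
  ss <- check_sufficient_stats(Sigma, Gamma)
  Sigma <- ss$Sigma; Gamma <- ss$Gamma
  stopifnot(alpha >= 0, alpha <= 1, tol > 0, maxiter >= 1)

  ev_min <- NULL
  if (is.null(lambda)) {
    lmax <- max(apply(Gamma, 2, lambda_max, alpha = alpha))
    lambda <- lambda_grid(lmax, nlambda = nlambda, min_ratio = min_ratio)
  } else {
    lambda <- as.numeric(lambda)
    if (any(lambda < 0)) stop("`lambda` values must be non-negative")
    if (length(lambda) > 1 && any(diff(lambda) >= 0)) {
      stop("`lambda` must be strictly decreasing")
    }
  }

  res <- .cd_solve(Sigma, Gamma, lambda, alpha, tol, as.integer(maxiter),
                   warm_start)
  beta <- lapply(res$beta, function(B) {
    dimnames(B) <- list(rownames(Sigma), NULL)
    as(Matrix::Matrix(B, sparse = TRUE), "CsparseMatrix")
  })
  names(beta) <- colnames(Gamma)
  if (!all(res$converged)) {
    warning(sum(!res$converged), " lambda/response combination(s) did not ",
            "converge in ", maxiter, " sweeps")
  }
  new_coef_path(lambda = lambda, beta = beta, iterations = res$iterations,
                converged = res$converged, alpha = alpha, tol = tol,
                solver = "coordinate_descent")
}

new_coef_path <- function(lambda, beta, iterations, converged, alpha, tol,
                          solver) {
  structure(list(lambda = lambda, beta = beta, iterations = iterations,
                 converged = converged, alpha = alpha, tol = tol,
                 solver = solver,
                 p = nrow(beta[[1]]), nresp = length(beta)),
            class = "coef_path")
}

#' @export
#' @method print coef_path
print.coef_path <- function(x, ...) {
  cat("<coef_path> ", x$solver, "\n",
      "  p = ", x$p, ", responses = ", x$nresp,
      ", lambda grid = ", length(x$lambda),
      " [", format(max(x$lambda), digits = 4), " .. ",
      format(min(x$lambda), digits = 4), "]\n",
      "  alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Extract coefficients from a path
#'
#' @param object A `coef_path`.
#' @param lambda_index Integer indices into the grid (default: all).
#' @param response Response column (index or name; default 1).
#' @param ... Unused.
#' @return Dense p x length(lambda_index) matrix.
#' @export
coef.coef_path <- function(object, lambda_index = NULL, response = 1, ...) {
  B <- object$beta[[response]]
  if (is.null(lambda_index)) lambda_index <- seq_along(object$lambda)
  as.matrix(B[, lambda_index, drop = FALSE])
}

#' LASSO/LAR path by least-angle regression on sufficient statistics
#'
#' Computes the full piecewise-linear coefficient path of the L1-penalized
#' quadratic objective, from `lambda = max |Gamma_j|` (all-zero solution)
#' down to `lambda = 0` (the unpenalized solve `Sigma^-1 Gamma`).  With
#' `method = "LASSO"` a variable whose coefficient crosses zero is dropped
#' from the active set (the lasso modification of LARS); with
#' `method = "LAR"` variables only ever join.  Ties when a variable enters
#' are broken by lowest index.  `Sigma` must be positive definite on every
#' active set encountered; a singular active-set system is an error
#' (duplicate predictors cannot be ordered meaningfully).
#'
#' @param Sigma Symmetric p x p matrix.
#' @param Gamma p-vector, or p x m matrix (a list of per-column paths is
#'   returned for m > 1, since breakpoint sets differ per column).
#' @param method `"LASSO"` (default) or `"LAR"`.
#' @param eps Numerical tolerance for event detection.
#' @return A `coef_path` whose `lambda` holds the breakpoints (decreasing,
#'   ending at 0) and whose `beta` holds the solutions at each breakpoint;
#'   or a list of such objects for matrix `Gamma`.
#' @export
lars_path <- function(Sigma, Gamma, method = c("LASSO", "LAR"), eps = 1e-10) {
  method <- match.arg(method)
  ss <- check_sufficient_stats(Sigma, Gamma)
  Sigma <- ss$Sigma; Gamma <- ss$Gamma
  if (ncol(Gamma) > 1) {
    return(lapply(seq_len(ncol(Gamma)),
                  function(j) lars_path(Sigma, Gamma[, j], method = method,
                                        eps = eps)))
  }
  gamma <- as.numeric(Gamma)
  p <- length(gamma)
  if (p > 1 && anyDuplicated(t(Sigma))) {
    stop("duplicate predictors detected (identical columns of `Sigma`); ",
         "the LARS entry order is undefined for exact duplicates")
  }

  beta <- numeric(p)
  lambdas <- numeric(0)
  betas <- list()
  A <- integer(0)

  repeat {
    cvec <- gamma - as.numeric(Sigma %*% beta)
    C <- max(abs(cvec))
    lambdas <- c(lambdas, max(C, 0))
    betas[[length(betas) + 1L]] <- beta
    if (C <= eps) break

    if (length(A) == 0) {
      A <- which(abs(cvec) >= C - eps * max(1, C))[1]  # lowest-index tie-break
    }
    sA <- sign(cvec[A])
    w <- tryCatch(solve(Sigma[A, A, drop = FALSE], sA), error = function(e) {
      stop("singular active-set system at step ", length(lambdas),
           " (active set: ", paste(A, collapse = ", "), "); ",
           "Sigma may contain duplicate predictors", call. = FALSE)
    })
    a <- as.numeric(Sigma[, A, drop = FALSE] %*% w)

    # largest admissible step drives the common correlation C to zero
    g_step <- C
    j_new <- NA_integer_
    inact <- setdiff(seq_len(p), A)
    for (j in inact) {
      for (g in c((C - cvec[j]) / (1 - a[j]), (C + cvec[j]) / (1 + a[j]))) {
        if (is.finite(g) && g > eps && g < g_step - eps) {
          g_step <- g
          j_new <- j
        }
      }
    }
    j_drop <- NA_integer_
    if (method == "LASSO" && length(A)) {
      dr <- -beta[A] / w
      dr[!is.finite(dr) | dr <= eps] <- Inf
      if (min(dr) < g_step - eps) {
        g_step <- min(dr)
        j_drop <- A[which.min(dr)]
        j_new <- NA_integer_
      }
    }

    beta[A] <- beta[A] + g_step * w
    if (!is.na(j_drop)) {
      beta[j_drop] <- 0
      A <- setdiff(A, j_drop)
    } else if (!is.na(j_new)) {
      A <- c(A, j_new)
    }
    if (length(lambdas) > 4 * p * p + 10) {
      stop("LARS failed to terminate; Sigma may be ill-conditioned")
    }
  }

  B <- do.call(cbind, betas)
  dimnames(B) <- list(rownames(Sigma), NULL)
  nl <- length(lambdas)
  new_coef_path(lambda = lambdas,
                beta = list(as(Matrix::Matrix(B, sparse = TRUE), "CsparseMatrix")),
                iterations = matrix(NA_integer_, nl, 1),
                converged = matrix(TRUE, nl, 1),
                alpha = 1, tol = eps, solver = paste0("lars_", tolower(method)))
}

#' KKT residuals of an Elastic-Net solution
#'
#' For each coefficient vector on the path, returns the largest violation of
#' the subgradient optimality conditions of the objective
#' `0.5 b'Sigma b - b'Gamma + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)`:
#' for nonzero coordinates `|Gamma_j - (Sigma b)_j - lambda(1-alpha)b_j -
#' lambda alpha sign(b_j)|`, for zero coordinates the excess of
#' `|Gamma_j - (Sigma b)_j|` over `lambda * alpha`.
#'
#' @param path A `coef_path`.
#' @param Sigma,Gamma The sufficient statistics the path was fitted to.
#' @return Matrix (nlambda x nresponses) of maximal KKT violations.
#' @export
kkt_violation <- function(path, Sigma, Gamma) {
  stopifnot(inherits(path, "coef_path"))
  Gamma <- as.matrix(Gamma)
  out <- matrix(NA_real_, length(path$lambda), path$nresp)
  for (r in seq_len(path$nresp)) {
    B <- as.matrix(path$beta[[r]])
    SB <- Sigma %*% B
    for (l in seq_along(path$lambda)) {
      lam <- path$lambda[l]
      b <- B[, l]
      grad <- Gamma[, r] - SB[, l] - lam * (1 - path$alpha) * b
      nz <- b != 0
      v <- 0
      if (any(nz)) v <- max(abs(grad[nz] - lam * path$alpha * sign(b[nz])))
      if (any(!nz)) v <- max(v, max(pmax(abs(grad[!nz]) - lam * path$alpha, 0)))
      out[l, r] <- v
    }
  }
  out
}
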