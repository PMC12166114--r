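# Sparse genomic prediction: single-trait, multi-trait, and selection indices.

#' Stacked phenotype index
#'
#' Maps each record of a stacked multi-trait/environment phenotype vector to
#' a genotype (row of the relationship matrix `K`) and a trait/environment
#' (row of the covariance matrices `Omega`/`R`), and partitions the records
#' into training and testing sets.
#'
#' @param ID_geno Integer vector: genotype row of `K` for each record.
#' @param ID_trait Integer vector: trait index for each record (default:
#'   all 1, the single-trait case).
#' @param trn,tst Disjoint integer sets of record indices.
#' @return Object of class `stacked_index`: list with a `records` tibble
#'   (`record`, `geno`, `trait`, `set`) and integer vectors `trn`, `tst`.
#' @export
stacked_index <- function(ID_geno, ID_trait = rep(1L, length(ID_geno)),
                          trn, tst = integer(0)) {
  ID_geno <- as.integer(ID_geno)
  ID_trait <- as.integer(ID_trait)
  nrec <- length(ID_geno)
  if (length(ID_trait) != nrec) stop("`ID_geno` and `ID_trait` lengths differ")
  if (anyDuplicated(cbind(ID_geno, ID_trait))) {
    stop("duplicate (genotype, trait) pairs in the stacked index")
  }
  trn <- sort(unique(as.integer(trn)))
  tst <- sort(unique(as.integer(tst)))
  if (length(intersect(trn, tst))) stop("`trn` and `tst` must be disjoint")
  idx <- c(trn, tst)
  if (length(idx) && (min(idx) < 1 || max(idx) > nrec)) {
    stop("record indices out of range 1..", nrec)
  }
  set <- rep(NA_character_, nrec)
  set[trn] <- "trn"; set[tst] <- "tst"
  structure(list(records = tibble::tibble(record = seq_len(nrec),
                                          geno = ID_geno, trait = ID_trait,
                                          set = set),
                 trn = trn, tst = tst),
            class = "stacked_index")
}

#' @export
#' @method print stacked_index
print.stacked_index <- function(x, ...) {
  cat("<stacked_index> ", nrow(x$records), " records (",
      length(unique(x$records$geno)), " genotypes x ",
      length(unique(x$records$trait)), " traits): ",
      length(x$trn), " training, ", length(x$tst), " testing\n", sep = "")
  invisible(x)
}

check_cov_params <- function(Omega, R = NULL, q_needed = 1) {
  as_cov <- function(M, name) {
    if (is.null(M)) return(NULL)
    if (length(M) == 1 && !is.matrix(M)) M <- matrix(as.numeric(M), 1, 1)
    M <- as.matrix(M)
    if (nrow(M) != ncol(M)) stop("`", name, "` must be square")
    if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
      stop("`", name, "` must be symmetric")
    }
    if (any(diag(M) <= 0)) stop("`", name, "` must have positive diagonal")
    M
  }
  Omega <- as_cov(Omega, "Omega")
  R <- as_cov(R, "R")
  if (!is.null(Omega) && nrow(Omega) < q_needed) {
    stop("`Omega` is ", nrow(Omega), "x", nrow(Omega),
         " but trait indices reach ", q_needed)
  }
  if (!is.null(R) && !is.null(Omega) && nrow(R) != nrow(Omega)) {
    stop("`Omega` and `R` dimensions differ")
  }
  list(Omega = Omega, R = R)
}

idx_cols <- function(idx) {
  if (is.data.frame(idx)) {
    list(geno = as.integer(idx$geno), trait = as.integer(idx$trait))
  } else if (is.matrix(idx)) {
    list(geno = as.integer(idx[, 1]), trait = as.integer(idx[, 2]))
  } else {
    stop("index sets must be data frames (geno, trait) or two-column matrices")
  }
}

#' Phenotypic covariance block of stacked records
#'
#' Entry (i, j) is `Omega[t_i, t_j] * K[g_i, g_j] + R[t_i, t_j] * 1(g_i = g_j)`,
#' i.e. the (`rows`, `cols`) block of the stacked phenotype covariance
#' `(Omega %x% K) + (R %x% I)` under the given genotype/trait maps.  The full
#' Kronecker product is never materialized; only the requested block is built.
#'
#' @param K n x n relationship matrix.
#' @param Omega,R q x q genetic and error (co)variance matrices (scalars are
#'   treated as 1 x 1).
#' @param rows,cols Record index sets: data frames with integer columns
#'   `geno` and `trait` (or two-column matrices in that order).
#' @return A `length(rows) x length(cols)` matrix.
#' @export
build_P <- function(K, Omega, R, rows, cols = rows) {
  cp <- check_cov_params(Omega, R)
  r <- idx_cols(rows); co <- idx_cols(cols)
  n <- nrow(K)
  q <- nrow(cp$Omega)
  if (max(r$geno, co$geno) > n || min(r$geno, co$geno) < 1) {
    stop("genotype indices out of range 1..", n)
  }
  if (max(r$trait, co$trait) > q || min(r$trait, co$trait) < 1) {
    stop("trait indices out of range 1..", q)
  }
  cp$Omega[r$trait, co$trait, drop = FALSE] * K[r$geno, co$geno, drop = FALSE] +
    cp$R[r$trait, co$trait, drop = FALSE] * outer(r$geno, co$geno, "==")
}

#' Genetic covariance block of stacked records
#'
#' As [build_P()] with the error term omitted: entry (i, j) is
#' `Omega[t_i, t_j] * K[g_i, g_j]`, the (`rows`, `cols`) block of
#' `Omega %x% K`.
#'
#' @inheritParams build_P
#' @return A `length(rows) x length(cols)` matrix.
#' @export
build_G <- function(K, Omega, rows, cols = rows) {
  Omega <- check_cov_params(Omega)$Omega
  r <- idx_cols(rows); co <- idx_cols(cols)
  n <- nrow(K)
  q <- nrow(Omega)
  if (max(r$geno, co$geno) > n || min(r$geno, co$geno) < 1) {
    stop("genotype indices out of range 1..", n)
  }
  if (max(r$trait, co$trait) > q || min(r$trait, co$trait) < 1) {
    stop("trait indices out of range 1..", q)
  }
  Omega[r$trait, co$trait, drop = FALSE] * K[r$geno, co$geno, drop = FALSE]
}

#' Sparse genomic prediction (single- or multi-trait)
#'
#' Builds the training covariance `P = (Omega %x% K + R %x% I)[trn, trn]` and
#' the training-testing genetic covariance `G = (Omega %x% K)[trn, tst]`
#' under the genotype/trait index maps, then solves, for every testing
#' record, the penalized problem
#' \deqn{\hat w_i = \arg\min_w \tfrac12 w'P w - w'G_i + \lambda F(w)}
#' over a decreasing `lambda` grid (shared across testing records, sized
#' from the largest per-record [lambda_max()]).  The rows of the resulting
#' weight matrices `W(lambda)` are sparse: each testing record is predicted
#' from a subset of the training records.  `lambda = 0` is solved by a
#' direct symmetric solve, so it reproduces (MT-)GBLUP exactly.
#'
#' For a single trait (`q = 1`), `varU`/`varE` are scalars; if omitted they
#' are estimated from the training records with [fit_blup()], and a GLS
#' intercept is profiled out so that `lambda = 0` predictions equal the
#' GBLUP output of [fit_blup()].  For `q > 1`, `varU` and `varE` are the
#' q x q matrices `Omega` and `R`, phenotypes are assumed centered
#' (adjusted for non-genetic effects), and predictions are `W(lambda) %*%
#' y_trn` with no intercept.
#'
#' @param y Optional stacked phenotype vector (one entry per record).  When
#'   supplied, predictions for the testing records are returned in `$yHat`.
#' @param K n x n genomic relationship matrix.
#' @param varU,varE Genetic and error (co)variance: scalars for `q = 1`, or
#'   q x q matrices `Omega`, `R` for `q > 1`.
#' @param trn,tst Record index sets (1-based), or pass `index`.
#' @param ID_geno,ID_trait Record-to-genotype and record-to-trait maps
#'   (defaults: records are genotypes 1..n of a single trait).
#' @param index Optionally a [stacked_index()] carrying all four of the
#'   above.
#' @param alpha Elastic-Net mixing parameter in \[0, 1\].
#' @param lambda Optional decreasing penalty grid; may include 0.  Default:
#'   [lambda_grid()] with `nlambda` values from the largest per-record
#'   lambda-max.
#' @param nlambda,min_ratio Grid size/span when `lambda` is `NULL`.
#' @param tol,maxiter Coordinate-descent control.
#' @param method Variance-estimation criterion when `varU`/`varE` are
#'   omitted (`q = 1` only).
#' @return Object of class `sgp`: list with `lambda`, `weights` (list of
#'   sparse `n_tst x n_trn` [Matrix::dgCMatrix] per lambda), `nsup`
#'   (average support size per lambda), `yHat` (n_tst x nlambda matrix, if
#'   `y` given), `varU`, `varE`, `intercept`, index maps, and solver
#'   diagnostics.
#' @seealso [predict.sgp()], [nsup_summary()], [kfold_cv_lambda()]
#' @export
sgp <- function(y = NULL, K, varU = NULL, varE = NULL,
                trn = NULL, tst = NULL, ID_geno = NULL, ID_trait = NULL,
                index = NULL, alpha = 1, lambda = NULL, nlambda = 100,
                min_ratio = 1e-4, tol = 1e-4, maxiter = 1000,
                method = c("REML", "ML")) {
  method <- match.arg(method)
  K <- as.matrix(K)
  n <- nrow(K)
  if (!is.null(index)) {
    stopifnot(inherits(index, "stacked_index"))
    ID_geno <- index$records$geno
    ID_trait <- index$records$trait
    if (is.null(trn)) trn <- index$trn
    if (is.null(tst)) tst <- index$tst
  }
  if (is.null(ID_geno)) ID_geno <- seq_len(n)
  if (is.null(ID_trait)) ID_trait <- rep(1L, length(ID_geno))
  ID_geno <- as.integer(ID_geno); ID_trait <- as.integer(ID_trait)
  nrec <- length(ID_geno)
  if (max(ID_geno) > n) stop("`ID_geno` references genotypes beyond nrow(K)")
  if (is.null(trn) || length(trn) == 0) stop("`trn` must be non-empty")
  if (is.null(tst) || length(tst) == 0) stop("`tst` must be non-empty")
  trn <- as.integer(trn); tst <- as.integer(tst)
  if (length(intersect(trn, tst))) stop("`trn` and `tst` must be disjoint")
  if (!is.null(y) && length(y) != nrec) {
    stop("`y` must have one entry per record (", nrec, ")")
  }
  q <- max(ID_trait)

  fb <- NULL
  if (is.null(varU) || is.null(varE)) {
    if (q > 1) stop("`varU` (Omega) and `varE` (R) must be supplied for q > 1")
    if (is.null(y)) stop("`y` is required to estimate varU/varE from training data")
    Krec <- K[ID_geno, ID_geno, drop = FALSE]
    fb <- fit_blup(y, Krec, trn = trn, method = method)
    varU <- fb$varU; varE <- fb$varE
  }
  cp <- check_cov_params(varU, varE, q_needed = q)
  Omega <- cp$Omega; R <- cp$R

  recs <- data.frame(geno = ID_geno, trait = ID_trait)
  P <- build_P(K, Omega, R, recs[trn, ], recs[trn, ])
  G <- build_G(K, Omega, recs[trn, ], recs[tst, ])

  alpha_eff <- max(alpha, 1e-3)  # grid sizing only (ridge has no finite lambda-max)
  if (is.null(lambda)) {
    lmax <- max(abs(G)) / alpha_eff
    if (lmax <= 0) stop("degenerate input: all training-testing genetic covariances are zero")
    lambda <- lambda_grid(lmax, nlambda = nlambda, min_ratio = min_ratio)
  } else {
    lambda <- as.numeric(lambda)
    if (any(lambda < 0)) stop("`lambda` must be non-negative")
    if (is.unsorted(rev(lambda), strictly = TRUE)) {
      stop("`lambda` must be strictly decreasing")
    }
  }

  n_trn <- length(trn); n_tst <- length(tst)
  pos <- lambda > 0
  path <- NULL
  if (any(pos)) {
    path <- solve_elastic_net(P, G, alpha = alpha, lambda = lambda[pos],
                              tol = tol, maxiter = maxiter)
  }
  W0 <- if (any(!pos)) t(solve(P, G)) else NULL  # direct (MT-)GBLUP solve

  weights <- vector("list", length(lambda))
  li_pos <- 0
  for (l in seq_along(lambda)) {
    if (lambda[l] > 0) {
      li_pos <- li_pos + 1
      Bl <- do.call(cbind, lapply(path$beta, function(B) B[, li_pos, drop = FALSE]))
      weights[[l]] <- as(Matrix::t(Bl), "CsparseMatrix")
    } else {
      weights[[l]] <- as(Matrix::Matrix(W0, sparse = TRUE), "CsparseMatrix")
    }
  }
  nsup <- vapply(weights, function(W) mean(Matrix::rowSums(W != 0)), numeric(1))

  intercept <- 0
  if (q == 1) {
    if (!is.null(fb)) {
      intercept <- fb$intercept
    } else if (!is.null(y)) {
      Pinv1 <- solve(P, rep(1, n_trn))
      intercept <- sum(Pinv1 * y[trn]) / sum(Pinv1)
    }
  }

  out <- structure(list(lambda = lambda, weights = weights, nsup = nsup,
                        alpha = alpha, tol = tol, q = q,
                        varU = Omega, varE = R, intercept = intercept,
                        trn = trn, tst = tst,
                        ID_geno = ID_geno, ID_trait = ID_trait,
                        iterations = if (!is.null(path)) path$iterations,
                        converged = if (!is.null(path)) path$converged,
                        blup_fit = fb),
                   class = "sgp")
  if (!is.null(y)) out$yHat <- predict(out, y = y)
  out
}

#' @export
#' @method print sgp
print.sgp <- function(x, ...) {
  cat("<sgp> q = ", x$q, ", n(trn) = ", length(x$trn),
      ", n(tst) = ", length(x$tst), ", alpha = ", x$alpha, "\n",
      "  lambda grid: ", length(x$lambda), " values [",
      format(max(x$lambda), digits = 4), " .. ",
      format(min(x$lambda), digits = 4), "]\n",
      "  nsup range: ", format(min(x$nsup), digits = 4), " .. ",
      format(max(x$nsup), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predictions from sparse prediction weights
#'
#' Computes `g_hat_tst(lambda) = W(lambda) %*% y_trn` for every lambda on
#' the grid.  For a single trait the fitted intercept is removed from the
#' training phenotypes and added back to the predictions; for q > 1
#' phenotypes are assumed adjusted (no intercept).
#'
#' @param object An `sgp` fit.
#' @param y Stacked phenotype vector, either full length (one entry per
#'   record) or of length `n_trn` (training records, in `trn` order).
#' @param ... Unused.
#' @return `n_tst x nlambda` matrix of predictions.
#' @export
predict.sgp <- function(object, y, ...) {
  n_trn <- length(object$trn)
  if (length(y) == n_trn) {
    y_trn <- y
  } else if (length(y) == length(object$ID_geno)) {
    y_trn <- y[object$trn]
  } else {
    stop("`y` must have length n_trn (", n_trn, ") or one entry per record (",
         length(object$ID_geno), ")")
  }
  if (anyNA(y_trn)) stop("training phenotypes contain missing values")
  yc <- y_trn - object$intercept
  out <- vapply(object$weights, function(W) as.numeric(W %*% yc),
                numeric(length(object$tst)))
  out <- matrix(out, nrow = length(object$tst)) + object$intercept
  dimnames(out) <- list(NULL, paste0("lambda_", seq_along(object$lambda)))
  out
}

#' Apply a weight path to a training phenotype vector
#'
#' Sparse-aware matrix-vector product `W(lambda) %*% y_trn` per lambda, with
#' no intercept handling (the raw prediction equation).
#'
#' @param result An `sgp` fit.
#' @param y_trn Numeric vector of length `n_trn`.
#' @return `n_tst x nlambda` matrix.
#' @export
predict_from_weights <- function(result, y_trn) {
  stopifnot(inherits(result, "sgp"))
  if (length(y_trn) != length(result$trn)) {
    stop("`y_trn` must have length ", length(result$trn))
  }
  out <- vapply(result$weights, function(W) as.numeric(W %*% y_trn),
                numeric(length(result$tst)))
  matrix(out, nrow = length(result$tst),
         dimnames = list(NULL, paste0("lambda_", seq_along(result$lambda))))
}

#' Sparse selection index
#'
#' Solves the penalized mean-squared-prediction-error problem of a
#' selection index,
#' \deqn{\hat w = \arg\min_w \tfrac12 w'P_x w - w'G_{xy} + \lambda F(w),}
#' where `Px` is the phenotypic (co)variance matrix of the measured
#' (indicator) traits and `Gxy` holds genetic covariances between the
#' indicator traits and the selection objective(s).  At `lambda = 0` this
#' is the classical Smith-Hazel index `w = Px^{-1} Gxy`; positive `lambda`
#' selects a subset of the indicator traits.  This is [solve_elastic_net()]
#' with `(Sigma, Gamma) = (Px, Gxy)`; the result additionally supports
#' `predict(fit, X)` to evaluate the index on candidate trait records.
#'
#' @param Px Symmetric p x p phenotypic covariance matrix.
#' @param Gxy p-vector (or p x m matrix) of genetic covariances.
#' @inheritParams solve_elastic_net
#' @return A `coef_path` with additional class `ssi`.
#' @export
solve_ssi <- function(Px, Gxy, alpha = 1, lambda = NULL, nlambda = 100,
                      min_ratio = 1e-4, tol = 1e-4, maxiter = 1000) {
  fit <- solve_elastic_net(Px, Gxy, alpha = alpha, lambda = lambda,
                           nlambda = nlambda, min_ratio = min_ratio,
                           tol = tol, maxiter = maxiter)
  class(fit) <- c("ssi", class(fit))
  fit
}

#' Evaluate a selection index on candidate records
#'
#' @param object An `ssi` fit.
#' @param X Matrix of indicator-trait records (individuals x traits).
#' @param response Response column of the index (default 1).
#' @param ... Unused.
#' @return `nrow(X) x nlambda` matrix of index values `X %*% w(lambda)`.
#' @export
predict.ssi <- function(object, X, response = 1, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p) stop("`X` must have ", object$p, " columns")
  out <- as.matrix(X %*% object$beta[[response]])
  dimnames(out) <- list(rownames(X), paste0("lambda_", seq_along(object$lambda)))
  out
}
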