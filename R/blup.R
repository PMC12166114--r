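# Single-component mixed model: y = mu + u + e, u ~ (0, varU * K), e ~ (0, varE * I).

#' Fit a GBLUP mixed model with a single genetic variance component
#'
#' Fits `y = mu*1 + u + e` with `u ~ (0, sigma_u^2 K)` and
#' `e ~ (0, sigma_e^2 I)` on the training subset by profiling the
#' (restricted) log-likelihood over the variance ratio
#' `r = sigma_u^2 / sigma_e^2`.  `K[trn, trn]` is eigendecomposed once; the
#' rotated model is diagonal, so each evaluation of the profile criterion is
#' O(n).  The ratio is optimized by Brent search on `log r` in \[-10, 10\]
#' (natural log) with tolerance 1e-8; `sigma_e^2` and the intercept are then
#' back-solved, and BLUPs are returned for all genotypes:
#' `g_hat = sigma_u^2 K[, trn] (sigma_u^2 K[trn, trn] + sigma_e^2 I)^{-1}
#' (y_trn - mu)`.
#'
#' The only fixed effect is an intercept (phenotypes are assumed adjusted
#' for non-genetic effects).  A solution at the edge of the search interval
#' is flagged via `boundary`; a flat profile (e.g. `K = I`, where the two
#' variances are not separately identifiable) is flagged via `flat` with a
#' warning.
#'
#' @param y Numeric n-vector of phenotypes; may contain `NA`.
#' @param K n x n relationship matrix covering all genotypes.
#' @param trn Indices of training records (default: all non-missing
#'   entries of `y`); must index observed entries, at least 10.
#' @param method `"REML"` (default) or `"ML"`.
#' @return Object of class `blup_fit`: list with `varU`, `varE`, `h2`,
#'   `intercept`, `loglik` (profile criterion at the optimum), `method`,
#'   `boundary`, `flat`, `u` (BLUP genetic values, all n), `yHat`
#'   (`intercept + u`), `trn`.
#' @seealso [tidy.blup_fit()], [glance.blup_fit()], [sgp()]
#' @export
fit_blup <- function(y, K, trn = NULL, method = c("REML", "ML")) {
  method <- match.arg(method)
  K <- as.matrix(K)
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n) {
    stop("`K` must be a square matrix matching length(y) = ", n)
  }
  if (is.null(trn)) trn <- which(!is.na(y))
  trn <- sort(unique(as.integer(trn)))
  if (any(trn < 1 | trn > n)) stop("`trn` indices out of range")
  if (anyNA(y[trn])) stop("`trn` must index observed (non-missing) entries of `y`")
  nt <- length(trn)
  if (nt < 10) stop("at least 10 training records are required, got ", nt)
  yt <- y[trn]
  if (var(yt) == 0) stop("degenerate input: zero phenotypic variance in the training set")

  eg <- eigen(K[trn, trn, drop = FALSE], symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-8 * max(abs(d))) {
    stop("K[trn, trn] is not positive semidefinite (min eigenvalue ",
         format(min(d)), ")")
  }
  d <- pmax(d, 0)
  U <- eg$vectors
  ytil <- as.numeric(crossprod(U, yt))
  xtil <- as.numeric(crossprod(U, rep(1, nt)))

  profile <- function(logr) {
    r <- exp(logr)
    w <- r * d + 1
    xx <- sum(xtil^2 / w)
    mu <- sum(xtil * ytil / w) / xx
    rss <- sum((ytil - xtil * mu)^2 / w)
    if (method == "REML") {
      -0.5 * ((nt - 1) * log(rss) + sum(log(w)) + log(xx))
    } else {
      -0.5 * (nt * log(rss) + sum(log(w)))
    }
  }

  lo <- -10; hi <- 10
  # flat-profile (non-identifiability) check, e.g. K proportional to I
  probe <- vapply(c(lo, -5, 0, 5, hi), profile, numeric(1))
  flat <- (max(probe) - min(probe)) < 1e-7 * (1 + abs(max(probe)))
  opt <- optimize(profile, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  logr <- opt$maximum
  boundary <- (logr - lo < 1e-3) || (hi - logr < 1e-3)
  if (flat) {
    warning("profile likelihood is flat: varU and varE are not separately ",
            "identifiable for this K (e.g. K = I); estimates are arbitrary ",
            "along the ridge")
  }

  r <- exp(logr)
  w <- r * d + 1
  xx <- sum(xtil^2 / w)
  mu <- sum(xtil * ytil / w) / xx
  rss <- sum((ytil - xtil * mu)^2 / w)
  varE <- if (method == "REML") rss / (nt - 1) else rss / nt
  varU <- r * varE
  h2 <- varU / (varU + varE)

  # BLUPs for all genotypes: varU * K[, trn] %*% Vinv %*% (y_trn - mu)
  alpha <- U %*% (as.numeric(crossprod(U, yt - mu)) / (varU * d + varE))
  u <- as.numeric(varU * K[, trn, drop = FALSE] %*% alpha)
  names(u) <- rownames(K)

  structure(list(varU = varU, varE = varE, h2 = h2, intercept = mu,
                 loglik = opt$objective, method = method,
                 boundary = boundary, flat = flat,
                 u = u, yHat = mu + u, trn = trn, n = n),
            class = "blup_fit")
}

#' @export
#' @method print blup_fit
print.blup_fit <- function(x, ...) {
  cat("<blup_fit> ", x$method, " single-component GBLUP\n",
      "  n(trn) = ", length(x$trn), " of ", x$n, "\n",
      "  varU = ", format(x$varU, digits = 4),
      ", varE = ", format(x$varE, digits = 4),
      ", h2 = ", format(x$h2, digits = 4),
      ", intercept = ", format(x$intercept, digits = 4), "\n", sep = "")
  if (x$boundary) cat("  note: variance-ratio estimate at search boundary\n")
  if (x$flat) cat("  note: flat profile; variances not identifiable\n")
  invisible(x)
}

#' @export
predict.blup_fit <- function(object, ...) object$yHat

#' Moment estimate of the genetic covariance between two traits
#'
#' Uses the polarization identity
#' `cov_g(y1, y2) = [varU(y1 + y2) - varU(y1) - varU(y2)] / 2`,
#' fitting [fit_blup()] to each composite trait on the common genotype set.
#' This is deliberately simple plumbing for testing multi-trait layers;
#' production estimates of a full genetic covariance matrix would come from
#' a multivariate mixed model.
#'
#' @param y1,y2 Numeric n-vectors observed on the same genotypes.
#' @param K n x n relationship matrix.
#' @param method Passed to [fit_blup()].
#' @return Scalar genetic covariance estimate.
#' @export
pairwise_genetic_covariance <- function(y1, y2, K, method = "REML") {
  stopifnot(length(y1) == length(y2))
  if (anyNA(y1) || anyNA(y2)) {
    keep <- which(!is.na(y1) & !is.na(y2))
    y1 <- y1[keep]; y2 <- y2[keep]; K <- K[keep, keep, drop = FALSE]
  }
  v12 <- fit_blup(y1 + y2, K, method = method)$varU
  v1 <- fit_blup(y1, K, method = method)$varU
  v2 <- fit_blup(y2, K, method = method)$varU
  (v12 - v1 - v2) / 2
}
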