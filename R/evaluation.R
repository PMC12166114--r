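# Training-testing partitioning, accuracy, CV for lambda, sparsity and bias summaries.

#' CV2 training-testing partition
#'
#' Implements the CV2 scheme for multi-trait/environment data: the record
#' grid is the complete n x q set of genotype-trait combinations, `n0`
#' genotypes are sampled without replacement to contribute testing data,
#' and each sampled genotype is assigned a random pair (`pair_size`
#' distinct traits) of its measurements as testing records.  Testing
#' genotypes therefore remain in the training set for their other
#' traits/environments, so prediction borrows information from the
#' candidates' own records on correlated traits.  The training set is all
#' remaining records: `n_trn = n*q - n0*pair_size`.
#'
#' @param n Number of genotypes.
#' @param q Number of traits/environments (record grid is complete n x q).
#' @param n0 Number of genotypes contributing testing records (0 < n0 <= n).
#' @param pair_size Testing records per sampled genotype (default 2, the
#'   "pair of measurements"); must be <= number of eligible traits.
#' @param traits Optional subset of trait indices from which testing pairs
#'   are drawn (e.g. one trait category of a larger grid); default all q.
#' @param seed Optional RNG seed for a reproducible partition.
#' @return A [stacked_index()] with records ordered trait-major
#'   (genotype 1..n of trait 1, then trait 2, ...).
#' @examples
#' part <- cv2_partition(n = 100, q = 4, n0 = 60, seed = 1)
#' length(part$trn) + length(part$tst) == 400
#' @export
cv2_partition <- function(n, q, n0, pair_size = 2, traits = NULL, seed = NULL) {
  stopifnot(n >= 1, q >= 1, n0 >= 1)
  if (n0 > n) stop("`n0` cannot exceed the number of genotypes n = ", n)
  if (is.null(traits)) traits <- seq_len(q)
  traits <- as.integer(traits)
  if (any(traits < 1 | traits > q)) stop("`traits` must be a subset of 1..q")
  if (pair_size > length(traits)) {
    stop("`pair_size` (", pair_size, ") exceeds the number of eligible traits (",
         length(traits), ")")
  }
  if (!is.null(seed)) set.seed(seed)

  ID_geno <- rep(seq_len(n), times = q)
  ID_trait <- rep(seq_len(q), each = n)
  geno_tst <- sample(n, n0)
  tst <- unlist(lapply(geno_tst, function(g) {
    tr <- traits[sample.int(length(traits), pair_size)]
    (tr - 1L) * n + g
  }))
  trn <- setdiff(seq_len(n * q), tst)
  stacked_index(ID_geno, ID_trait, trn = trn, tst = tst)
}

#' Benchmark CV2 layouts
#'
#' Named presets for the published crop-data layouts (genotype counts,
#' trait grids, and testing-set sizing), usable as
#' `do.call(cv2_partition, as.list(preset[, c("n","q","n0")]))` with
#' `traits = seq_len(trait_pool)`.
#'
#' @return Tibble with columns `preset`, `n`, `q`, `trait_pool`, `n0`,
#'   `pair_size`, and the implied `n_tst`/`n_trn` record counts.
#' @export
cv2_presets <- function() {
  out <- tibble::tribble(
    ~preset,            ~n,   ~q,  ~trait_pool, ~n0,
    "wheat",            3731L, 4L,  4L,          2238L,
    "maize_north",      4132L, 4L,  4L,          2478L,
    "maize_south",      1868L, 4L,  4L,          1116L,
    "rice_morphology",  413L,  20L, 4L,          240L,
    "rice_yield",       413L,  20L, 6L,          360L,
    "rice_seed",        413L,  20L, 5L,          300L,
    "rice_quality",     413L,  20L, 3L,          180L
  )
  out$pair_size <- 2L
  out$n_tst <- out$n0 * out$pair_size
  out$n_trn <- out$n * out$q - out$n_tst
  out
}

#' Within-trait prediction accuracy
#'
#' Pearson correlation between observed and predicted testing values,
#' computed separately within each trait/environment (never pooled across
#' traits, whose scales and means differ).
#'
#' @param y_tst Observed testing values.
#' @param g_hat Predicted values (same length/order).
#' @param ID_trait Trait index per testing record (default: one trait).
#' @param min_records Minimum records per trait (default 3); traits with
#'   fewer, or with zero variance in either vector, get `NA`.
#' @return Tibble with columns `trait`, `n`, `accuracy`.
#' @export
accuracy_by_trait <- function(y_tst, g_hat,
                              ID_trait = rep(1L, length(y_tst)),
                              min_records = 3) {
  stopifnot(length(y_tst) == length(g_hat), length(ID_trait) == length(y_tst))
  df <- tibble::tibble(trait = as.integer(ID_trait),
                       y = as.numeric(y_tst), g = as.numeric(g_hat))
  df |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = if (dplyr::n() < min_records ||
                     stats::sd(.data$y) == 0 || stats::sd(.data$g) == 0) {
        NA_real_
      } else {
        stats::cor(.data$y, .data$g)
      },
      .groups = "drop")
}

#' Support-size (sparsity) summary of an SGP fit
#'
#' `nsup(lambda)` is the average, over testing records, of the number of
#' training records with a non-zero weight.  With `by_trait = TRUE` the
#' supports are additionally decomposed by the trait/environment of the
#' contributing training records (the data behind sparsity-composition
#' area plots).
#'
#' @param result An `sgp` fit.
#' @param by_trait Also return the per-trait composition of the supports.
#' @return Tibble `(lambda_index, lambda, nsup)`, or with `by_trait` a
#'   tibble `(lambda_index, lambda, trait, n_nonzero, fraction)` where
#'   fractions sum to one over traits whenever `nsup > 0`.
#' @export
nsup_summary <- function(result, by_trait = FALSE) {
  stopifnot(inherits(result, "sgp"))
  base <- tibble::tibble(lambda_index = seq_along(result$lambda),
                         lambda = result$lambda, nsup = result$nsup)
  if (!by_trait) return(base)
  trait_trn <- result$ID_trait[result$trn]
  purrr::map_dfr(seq_along(result$lambda), function(l) {
    nz_per_trait <- vapply(sort(unique(trait_trn)), function(tr) {
      sum(Matrix::colSums(result$weights[[l]][, trait_trn == tr, drop = FALSE] != 0))
    }, numeric(1))
    tot <- sum(nz_per_trait)
    tibble::tibble(lambda_index = l, lambda = result$lambda[l],
                   trait = sort(unique(trait_trn)),
                   n_nonzero = nz_per_trait,
                   fraction = if (tot > 0) nz_per_trait / tot else NA_real_)
  })
}

#' Mean and slope bias of predictions
#'
#' Regresses observed on predicted values: `slope = cov(y, g_hat) /
#' var(g_hat)` and `bias = mean(y) - mean(g_hat)`.  A slope above one
#' indicates over-shrunk (under-dispersed) predictions.  Supply `ID_trait`
#' to compute the summaries within trait/environment.
#'
#' @param y_tst Observed values.
#' @param g_hat Predicted values.
#' @param ID_trait Optional trait index per record.
#' @return Tibble with columns `trait` (if grouped), `bias`, `slope`.
#' @export
bias_slope <- function(y_tst, g_hat, ID_trait = NULL) {
  stopifnot(length(y_tst) == length(g_hat))
  one <- function(y, g) {
    if (stats::var(g) == 0) stop("zero-variance predictions: slope undefined")
    tibble::tibble(bias = mean(y) - mean(g),
                   slope = stats::cov(y, g) / stats::var(g))
  }
  if (is.null(ID_trait)) return(one(y_tst, g_hat))
  tibble::tibble(trait = as.integer(ID_trait), y = y_tst, g = g_hat) |>
    dplyr::group_by(.data$trait) |>
    dplyr::reframe(one(.data$y, .data$g))
}

#' k-fold cross-validation for the penalty parameter
#'
#' Splits the training records into `k` folds (stratified by trait so every
#' fold carries records of every trait), fits an SGP to the other `k - 1`
#' folds with each fold in turn as pseudo-testing over one shared `lambda`
#' grid, scores within-trait accuracy per `lambda`, averages it across
#' traits (simple mean, omitting traits with too few records in a fold) and
#' folds, and returns the maximizer.  Ties are broken in favor of the
#' largest `lambda` (the sparsest model).  Only training records ever enter
#' this function, so the testing set cannot leak into the choice of
#' `lambda`.
#'
#' The shared grid is sized from the largest within-training genetic
#' covariance and, by default, includes `lambda = 0` so that selecting a
#' positive `lambda` is a genuine comparison against (MT-)GBLUP.
#'
#' @param y Stacked phenotype vector (one entry per record).
#' @param K Relationship matrix.
#' @param varU,varE Genetic and error (co)variance (see [sgp()]); for
#'   `q = 1` they may be omitted and are then estimated once on the full
#'   training set.
#' @param index A [stacked_index()] whose `trn` defines the training
#'   records (its `tst`, if any, is ignored here).
#' @param k Number of folds (default 10).
#' @param alpha,nlambda,min_ratio,tol,maxiter Passed to [sgp()].
#' @param include_zero Include `lambda = 0` as a CV candidate.
#' @param min_records Per-trait minimum fold records for accuracy.
#' @param seed Optional RNG seed for the fold assignment.
#' @return Object of class `sgp_cv`: list with `lambda`, `accuracy`
#'   (tibble fold x lambda x trait), `mean_accuracy` (tibble per lambda),
#'   `lambda_opt`, `folds` (tibble record/fold), `seed`.
#' @export
kfold_cv_lambda <- function(y, K, varU = NULL, varE = NULL, index, k = 10,
                            alpha = 1, nlambda = 100, min_ratio = 1e-4,
                            tol = 1e-4, maxiter = 1000, include_zero = TRUE,
                            min_records = 3, seed = NULL) {
  stopifnot(inherits(index, "stacked_index"), k >= 2)
  if (!is.null(seed)) set.seed(seed)
  trn <- index$trn
  ID_geno <- index$records$geno
  ID_trait <- index$records$trait
  q <- max(ID_trait[trn])

  if (is.null(varU) || is.null(varE)) {
    if (q > 1) stop("`varU`/`varE` must be supplied for q > 1")
    fb <- fit_blup(y, K[ID_geno, ID_geno, drop = FALSE], trn = trn)
    varU <- fb$varU; varE <- fb$varE
  }
  cp <- check_cov_params(varU, varE, q_needed = q)

  # fold assignment, stratified by trait
  fold <- integer(length(trn))
  for (tr in unique(ID_trait[trn])) {
    idx <- which(ID_trait[trn] == tr)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (min(table(fold)) < 1) stop("some fold received no records; reduce `k`")

  # one shared grid, sized from the largest within-training genetic covariance
  recs <- data.frame(geno = ID_geno, trait = ID_trait)
  Gtt <- build_G(K, cp$Omega, recs[trn, ], recs[trn, ])
  diag(Gtt) <- 0
  lmax <- max(abs(Gtt)) / max(alpha, 1e-3)
  lam <- lambda_grid(lmax, nlambda = nlambda, min_ratio = min_ratio)
  if (include_zero) lam <- c(lam, 0)

  acc <- purrr::map_dfr(seq_len(k), function(f) {
    tst_f <- trn[fold == f]
    trn_f <- trn[fold != f]
    fit <- sgp(y = y, K = K, varU = cp$Omega, varE = cp$R,
               trn = trn_f, tst = tst_f, ID_geno = ID_geno,
               ID_trait = ID_trait, alpha = alpha, lambda = lam,
               tol = tol, maxiter = maxiter)
    purrr::map_dfr(seq_along(lam), function(l) {
      a <- accuracy_by_trait(y[tst_f], fit$yHat[, l], ID_trait[tst_f],
                             min_records = min_records)
      a$fold <- f; a$lambda_index <- l; a$lambda <- lam[l]
      a
    })
  })

  mean_acc <- acc |>
    dplyr::group_by(.data$fold, .data$lambda_index, .data$lambda) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::group_by(.data$lambda_index, .data$lambda) |>
    dplyr::summarise(accuracy = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$lambda_index)

  # maximizer; exact ties broken toward the largest lambda (sparsest model)
  best <- which(mean_acc$accuracy == max(mean_acc$accuracy, na.rm = TRUE))
  opt_idx <- best[which.max(mean_acc$lambda[best])]

  structure(list(lambda = lam,
                 accuracy = acc,
                 mean_accuracy = mean_acc,
                 lambda_opt = mean_acc$lambda[opt_idx],
                 lambda_opt_index = mean_acc$lambda_index[opt_idx],
                 folds = tibble::tibble(record = trn, fold = fold),
                 k = k, alpha = alpha, seed = seed),
            class = "sgp_cv")
}

#' @export
#' @method print sgp_cv
print.sgp_cv <- function(x, ...) {
  cat("<sgp_cv> ", x$k, "-fold CV over ", length(x$lambda),
      " lambda values\n", "  lambda_opt = ", format(x$lambda_opt, digits = 4),
      " (index ", x$lambda_opt_index, "), mean accuracy ",
      format(x$mean_accuracy$accuracy[x$mean_accuracy$lambda_index ==
                                        x$lambda_opt_index], digits = 4),
      "\n", sep = "")
  invisible(x)
}
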