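# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a coefficient path
#'
#' One row per non-zero coefficient: `lambda_index`, `lambda`, `response`,
#' `predictor`, `estimate`.
#'
#' @param x A `coef_path`.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.coef_path <- function(x, ...) {
  purrr::map_dfr(seq_along(x$beta), function(r) {
    B <- as(x$beta[[r]], "TsparseMatrix")
    tibble::tibble(lambda_index = B@j + 1L,
                   lambda = x$lambda[B@j + 1L],
                   response = r,
                   predictor = B@i + 1L,
                   estimate = B@x)
  }) |> dplyr::arrange(.data$lambda_index, .data$response, .data$predictor)
}

#' One-row summary of a coefficient path
#'
#' @param x A `coef_path`.
#' @param ... Unused.
#' @return Tibble with `p`, `n_responses`, `n_lambda`, `lambda_max`,
#'   `lambda_min`, `alpha`, `n_converged`, `solver`.
#' @export
glance.coef_path <- function(x, ...) {
  tibble::tibble(p = x$p, n_responses = x$nresp, n_lambda = length(x$lambda),
                 lambda_max = max(x$lambda), lambda_min = min(x$lambda),
                 alpha = x$alpha, n_converged = sum(x$converged),
                 solver = x$solver)
}

#' Coefficient profile plot of a path
#'
#' Coefficient trajectories against `lambda` (log scale), one line per
#' predictor, faceted by response when there are several.
#'
#' @param object A `coef_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coef_path <- function(object, ...) {
  td <- tidy(object)
  full <- tidyr::expand_grid(
    lambda_index = seq_along(object$lambda),
    response = seq_along(object$beta),
    predictor = sort(unique(td$predictor))
  )
  full$lambda <- object$lambda[full$lambda_index]
  td <- dplyr::left_join(full, td,
                         by = c("lambda_index", "lambda", "response", "predictor"))
  td$estimate[is.na(td$estimate)] <- 0
  pl <- ggplot2::ggplot(td, ggplot2::aes(x = .data$lambda, y = .data$estimate,
                                         group = .data$predictor,
                                         colour = factor(.data$predictor))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "coefficient") +
    ggplot2::theme_minimal()
  if (length(object$beta) > 1) {
    pl <- pl + ggplot2::facet_wrap(~response)
  }
  pl
}

#' Tidy an SGP fit
#'
#' Non-zero prediction weights as triplets: `lambda_index`, `lambda`,
#' `response` (testing record, positional), `predictor` (training record,
#' positional), `weight`.
#'
#' @param x An `sgp` fit.
#' @param lambda_index Optional subset of grid indices.
#' @param ... Unused.
#' @return Tibble.
#' @export
tidy.sgp <- function(x, lambda_index = NULL, ...) {
  if (is.null(lambda_index)) lambda_index <- seq_along(x$lambda)
  purrr::map_dfr(lambda_index, function(l) {
    W <- as(x$weights[[l]], "TsparseMatrix")
    tibble::tibble(lambda_index = l, lambda = x$lambda[l],
                   response = W@i + 1L, predictor = W@j + 1L, weight = W@x)
  })
}

#' One-row summary of an SGP fit
#'
#' @param x An `sgp` fit.
#' @param ... Unused.
#' @return Tibble with problem sizes, grid span, and the sparsity range.
#' @export
glance.sgp <- function(x, ...) {
  tibble::tibble(q = x$q, n_trn = length(x$trn), n_tst = length(x$tst),
                 alpha = x$alpha, n_lambda = length(x$lambda),
                 lambda_max = max(x$lambda), lambda_min = min(x$lambda),
                 nsup_min = min(x$nsup), nsup_max = max(x$nsup))
}

#' Sparsity profile plot of an SGP fit
#'
#' Average support size `nsup(lambda)` against `lambda`; with
#' `by_trait = TRUE`, a stacked-area decomposition of the supports by the
#' trait/environment of the contributing training records.
#'
#' @param object An `sgp` fit.
#' @param by_trait Stack the per-trait composition (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sgp <- function(object, by_trait = FALSE, ...) {
  if (by_trait) {
    comp <- nsup_summary(object, by_trait = TRUE)
    base <- nsup_summary(object)
    comp <- dplyr::left_join(comp, base[, c("lambda_index", "nsup")],
                             by = "lambda_index")
    comp$contribution <- comp$fraction * comp$nsup
    return(ggplot2::ggplot(comp[comp$lambda > 0, ],
                           ggplot2::aes(x = .data$lambda,
                                        y = .data$contribution,
                                        fill = factor(.data$trait))) +
             ggplot2::geom_area() +
             ggplot2::scale_x_log10() +
             ggplot2::labs(x = expression(lambda), y = "nsup",
                           fill = "trait") +
             ggplot2::theme_minimal())
  }
  ns <- nsup_summary(object)
  ggplot2::ggplot(ns[ns$lambda > 0, ],
                  ggplot2::aes(x = .data$lambda, y = .data$nsup)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "average support size") +
    ggplot2::theme_minimal()
}

#' Tidy a GBLUP fit
#'
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @return Tibble with one row per genotype: `geno`, `u` (BLUP genetic
#'   value), `prediction`, `in_training`.
#' @export
tidy.blup_fit <- function(x, ...) {
  tibble::tibble(geno = seq_along(x$u), u = unname(x$u),
                 prediction = unname(x$yHat),
                 in_training = seq_along(x$u) %in% x$trn)
}

#' One-row summary of a GBLUP fit
#'
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @return Tibble with `varU`, `varE`, `h2`, `intercept`, `loglik`,
#'   `method`, `boundary`, `flat`, `n_trn`.
#' @export
glance.blup_fit <- function(x, ...) {
  tibble::tibble(varU = x$varU, varE = x$varE, h2 = x$h2,
                 intercept = x$intercept, loglik = x$loglik,
                 method = x$method, boundary = x$boundary, flat = x$flat,
                 n_trn = length(x$trn))
}

#' Tidy a cross-validation report
#'
#' @param x An `sgp_cv`.
#' @param ... Unused.
#' @return The per-fold, per-lambda, per-trait accuracy tibble.
#' @export
tidy.sgp_cv <- function(x, ...) x$accuracy

#' One-row summary of a cross-validation report
#'
#' @param x An `sgp_cv`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_lambda`, `lambda_opt`, `accuracy_opt`.
#' @export
glance.sgp_cv <- function(x, ...) {
  tibble::tibble(k = x$k, n_lambda = length(x$lambda),
                 lambda_opt = x$lambda_opt,
                 accuracy_opt = x$mean_accuracy$accuracy[
                   x$mean_accuracy$lambda_index == x$lambda_opt_index])
}

#' Cross-validated accuracy curve
#'
#' Mean cross-validated accuracy against `lambda`, with the selected
#' `lambda_opt` marked.  The `lambda = 0` candidate, when present, is drawn
#' at the left axis limit.
#'
#' @param object An `sgp_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sgp_cv <- function(object, ...) {
  ma <- object$mean_accuracy
  lam_pos <- ma$lambda[ma$lambda > 0]
  ma$lambda_plot <- ifelse(ma$lambda > 0, ma$lambda, min(lam_pos) / 2)
  ggplot2::ggplot(ma, ggplot2::aes(x = .data$lambda_plot,
                                   y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ma[ma$lambda_index == object$lambda_opt_index, ],
                        colour = "red", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "mean CV accuracy") +
    ggplot2::theme_minimal()
}
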