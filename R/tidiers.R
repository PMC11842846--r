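#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a distribution fit
#'
#' @param x A `dist_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.dist_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a distribution fit
#'
#' @param x A `dist_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `family`, `n`, `log_likelihood`,
#'   `ks_statistic`, `ks_p` and the fitted parameters.
#' @exportS3Method generics::glance
glance.dist_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(family = x$family, n = x$n,
           log_likelihood = x$log_likelihood,
           ks_statistic = x$ks_statistic, ks_p = x$ks_p),
    as_tibble(as.list(x$params))
  )
}

#' Tidy a correlation report
#'
#' @param x A `correlation_report` object.
#' @param ... Unused.
#' @return A one-row tibble mirroring a correlation-table row: variable
#'   names, n, Pearson and Spearman coefficients, Fisher-z interval,
#'   linear-fit slope and intercept, and permutation p.
#' @exportS3Method generics::tidy
tidy.correlation_report <- function(x, ...) {
  tibble(
    x_name = x$x_name, y_name = x$y_name, n = x$n,
    pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
    ci95_low = x$ci95_low, ci95_high = x$ci95_high,
    slope = unname(x$slope), intercept = unname(x$intercept),
    permutation_p = x$permutation_p
  )
}

#' @rdname tidy.correlation_report
#' @exportS3Method generics::glance
glance.correlation_report <- function(x, ...) tidy(x)

#' Tidy a prediction result
#'
#' @param x A `prediction_result` object.
#' @param ... Unused.
#' @return A tibble with one row per record: `measured`, `predicted`,
#'   `fold_id`.
#' @exportS3Method generics::tidy
tidy.prediction_result <- function(x, ...) {
  tibble(measured = x$measured, predicted = x$predicted,
         fold_id = x$fold_id)
}

#' One-row summary of a prediction result
#'
#' @param x A `prediction_result` object.
#' @param ... Unused.
#' @return A one-row tibble with `target`, `model`, `n`, `folds`,
#'   `n_predictors`, `prediction_r`.
#' @exportS3Method generics::glance
glance.prediction_result <- function(x, ...) {
  tibble(
    target = x$target, model = x$model, n = x$n, folds = x$folds,
    n_predictors = length(x$predictors), prediction_r = x$prediction_r
  )
}

#' Tidy a canonical correlation result
#'
#' @param x A `cca_result` object.
#' @param ... Unused.
#' @return A tibble with `component` and `canonical_correlation`.
#' @exportS3Method generics::tidy
tidy.cca_result <- function(x, ...) {
  tibble(
    component = seq_along(x$correlations),
    canonical_correlation = x$correlations
  )
}

#' Tidy a PCA result
#'
#' @param x A `pca_result` object.
#' @param ... Unused.
#' @return A tibble with `component` and `variance_fraction`.
#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) {
  tibble(
    component = seq_along(x$variance_fraction),
    variance_fraction = x$variance_fraction
  )
}
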