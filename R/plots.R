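#' Overlay normalized distributions and their master-curve fit
#'
#' Plots kernel density estimates of several normalized samples on a common
#' axis, optionally with the fitted log-normal or unit-mean gamma curve, to
#' visualize the collapse of mean-normalized area (or rescaled
#' aspect-ratio) distributions.
#'
#' @param groups Named list of normalized numeric vectors.
#' @param fit Optional `dist_fit` drawn as a dashed master curve.
#' @param log_x Use a logarithmic x axis (natural for area collapses).
#' @return A ggplot object.
#' @export
plot_collapse <- function(groups, fit = NULL, log_x = FALSE) {
  df <- purrr::imap_dfr(groups, function(v, nm) {
    tibble(group = nm, x = v)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x,
                                        colour = .data$group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "normalized value", y = "PDF", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xs <- seq(max(min(df$x), 1e-3), max(df$x), length.out = 256)
    ys <- if (fit$family == "lognormal") {
      stats::dlnorm(xs, fit$params[["mu"]], sqrt(fit$params[["sigma2"]]))
    } else {
      stats::dgamma(xs, fit$params[["k"]], rate = fit$params[["k"]])
    }
    p <- p + ggplot2::geom_line(
      data = tibble(x = xs, y = ys),
      ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, linetype = "dashed"
    )
  }
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.correlation_report <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = unname(object$slope),
                         intercept = unname(object$intercept),
                         colour = "firebrick") +
    ggplot2::labs(
      x = object$x_name, y = object$y_name,
      title = sprintf("r = %.3f [%.3f, %.3f], n = %d",
                      object$pearson_r, object$ci95_low,
                      object$ci95_high, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.autocorrelation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance,
                                       y = .data$correlation)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(alpha = !.data$flagged),
                        show.legend = FALSE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (µm)", y = "autocorrelation") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.prediction_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured,
                                   y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "firebrick") +
    ggplot2::labs(
      x = "measured", y = "predicted (out-of-fold)",
      title = sprintf("%s (%s): r = %.3f", object$target, object$model,
                      object$prediction_r)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.importance_ranking <- function(object, ...) {
  df <- dplyr::arrange(object, .data$rank)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_r, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "drop in prediction r on removal", y = NULL) +
    ggplot2::theme_minimal()
}

#' Display a labeled monolayer
#'
#' Draws the cell boundaries, nuclei, and optionally one intensity channel
#' of a labeled monolayer as a raster image.
#'
#' @param object A `labeled_monolayer`.
#' @param channel Optional channel name to shade nuclei by intensity.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.labeled_monolayer <- function(object, channel = NULL, ...) {
  ex <- label_exposures(object$cell_labels)
  boundary <- ex$up | ex$down | ex$left | ex$right
  W <- nrow(object$cell_labels)
  H <- ncol(object$cell_labels)
  img <- if (!is.null(channel)) {
    object$channels[[channel]]
  } else {
    (object$nucleus_labels > 0) * 1
  }
  df <- tibble(
    row = rep(seq_len(W), times = H),
    col = rep(seq_len(H), each = W),
    value = as.vector(img),
    boundary = as.vector(boundary)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_raster(
      data = df[df$boundary, ],
      fill = "white"
    ) +
    ggplot2::scale_fill_viridis_c(name = channel %||% "nucleus") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
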