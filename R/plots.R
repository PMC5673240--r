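# ggplot2 visualizations for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot significance counts per property from a correlation screen
#'
#' Bar chart of the number of genes significant per ephys property at each
#' configured FDR threshold.
#'
#' @param object A [screen_correlations()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_screen <- function(object, ...) {
  counts <- attr(object, "significance_counts")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$property,
                                       y = .data$n_significant,
                                       fill = factor(.data$alpha))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "ephys property", y = "significant genes",
                  fill = "FDR threshold") +
    ggplot2::theme_minimal()
}

#' Observed vs leave-one-out-predicted values for one property
#'
#' Scatter of held-out predictions against observations on the modeling
#' scale, with the unity line.
#'
#' @param object An [evaluate_loocv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s: LOOCV R² = %.2f", object$property,
                      object$r2_loocv),
      x = "observed (modeling scale)", y = "predicted (held out)") +
    ggplot2::theme_minimal()
}

#' Observed vs transferred predictions on the standardized scale
#'
#' Scatter of the transfer predictions against the independently
#' normalized observations, with the best linear fit (the transfer metric
#' tolerates affine miscalibration, so the fit line rather than the unity
#' line is shown).
#'
#' @param object A [transfer_predict()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transfer_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed_z, y = .data$predicted_z)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s: transfer R² = %.2f", object$property,
                      object$r2_transfer),
      x = "observed (z-scored)", y = "predicted (z-scored)") +
    ggplot2::theme_minimal()
}

#' Null distribution of a permutation test
#'
#' Histogram of the permuted statistic with the observed value marked.
#'
#' @param object A [permutation_null()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic_value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(
      title = sprintf("%s / %s: p = %.4g", object$property, object$statistic,
                      object$p_value),
      x = "permuted statistic", y = "count") +
    ggplot2::theme_minimal()
}

#' Scatter of one gene's expression against one ephys property
#'
#' The per-cell-type view underlying a single screen record.
#'
#' @param dataset A [paired_dataset()].
#' @param gene Gene id present in the dataset.
#' @param property Registered property code.
#' @return A ggplot object.
#' @export
plot_gene_property <- function(dataset, gene, property) {
  stopifnot(inherits(dataset, "paired_dataset"),
            gene %in% colnames(dataset$expression))
  assert_property(property)
  df <- tibble::tibble(
    cell_type = rownames(dataset$expression),
    expression = dataset$expression[, gene],
    ephys = dataset$ephys[, property]
  ) |> dplyr::filter(!is.na(.data$ephys))
  r <- spearman_with_p(df$expression, df$ephys)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expression, y = .data$ephys)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s vs %s: r_s = %.2f, p = %.2g", gene, property,
                      r$r_s, r$p_value),
      x = sprintf("%s expression", gene), y = property) +
    ggplot2::theme_minimal()
}
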