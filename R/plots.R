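#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cumulative feature importance of a lifestyle model
#'
#' Domains ranked by impurity importance against the cumulative share of
#' total importance they carry — the curve that shows how strongly the
#' model concentrates on a small core of domains.
#'
#' @param object A `lifestyle_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lifestyle_model
#' @export
autoplot.lifestyle_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cumulative_share)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "domains, ranked by importance",
      y = "cumulative share of feature importance",
      title = "Concentration of model weight across domains"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A [confusion_matrix()].
#' @param ... Unused.
#' @return A ggplot tile chart with counts overlaid.
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true, fill = .data$n)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted lifestyle", y = "true lifestyle") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of prediction confidence
#'
#' Histogram of the temperate-class probability over a set of
#' predictions; mass near 0 or 1 corresponds to confident virulent or
#' temperate calls, mass in the middle to uncertain genomes.
#'
#' @param predictions Prediction tibble from [predict.lifestyle_model()].
#' @param threshold Confidence threshold drawn as reference lines.
#' @return A ggplot.
#' @export
plot_confidence <- function(predictions, threshold = 0.95) {
  ggplot2::ggplot(predictions, ggplot2::aes(x = .data$p_temperate)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0, fill = "grey40") +
    ggplot2::geom_vline(
      xintercept = c(1 - threshold, threshold), linetype = "dashed"
    ) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "P(temperate)", y = "genomes",
      title = "Prediction confidence distribution"
    ) +
    ggplot2::theme_minimal()
}
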