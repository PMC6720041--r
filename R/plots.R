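# ggplot2 views of the result types. These are presentation helpers only;
# every number they draw comes from the tidy tables the evaluation and
# robustness functions already return.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a ROC or precision-recall curve
#'
#' @param object A `curve_result` from [roc_curve()] or [pr_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curve_result <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(direction = if (object$kind == "PR") "vh" else "hv",
                       linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = if (object$kind == "ROC") "False positive rate" else "Recall",
      y = if (object$kind == "ROC") "True positive rate" else "Precision",
      title = sprintf("%s curve (AUC = %.3f)", object$kind, object$auc)
    ) +
    ggplot2::theme_minimal()
  if (object$kind == "ROC") {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed", colour = "grey60")
  }
  p
}

#' Violin plot of robustness AUC distributions
#'
#' One violin per removal fraction, faceted by method: the standard view of
#' how performance decays as signature genes are removed or masked.
#'
#' @param object A `robustness_result` from [robustness_experiment()].
#' @param metric `"roc_auc"` or `"pr_auc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.robustness_result <- function(object, metric = c("roc_auc",
                                                          "pr_auc"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  df$fraction <- factor(df$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction,
                                   y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "#a6bddb", colour = "grey40", scale = "width") +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 1) +
    ggplot2::facet_wrap(~method) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Fraction of signature genes removed / masked",
                  y = toupper(sub("_auc", " AUC", metric))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a score matrix
#'
#' @param object A score matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$cell_type,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(title = paste("method:", attr(object, "method")),
                  x = "cluster", y = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
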