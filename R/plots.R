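#' Heatmap of immune population scores
#'
#' Displays per-population centered (not scaled) log2 scores, the
#' conventional display transform for cell-score heatmaps; centering is
#' applied for display only and never enters distance computations.
#'
#' @param object A `cell_scores` tibble.
#' @param order_samples Optional sample ordering (e.g. an hclust order
#'   from [cluster_samples()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_scores
#' @export
autoplot.cell_scores <- function(object, order_samples = NULL, ...) {
  m <- wide_to_matrix(object, "population")
  m <- m - rowMeans(m)
  long <- tidyr::pivot_longer(
    matrix_to_wide(m, "population"), -"population",
    names_to = "sample_id", values_to = "centered_score")
  if (!is.null(order_samples)) {
    long$sample_id <- factor(long$sample_id, levels = order_samples)
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$population,
                                     fill = .data$centered_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "centered\nlog2 score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Clustered score heatmap for a pipeline report
#'
#' @param object A `tme_report`.
#' @param ... Unused.
#' @return A ggplot object: the score heatmap with samples in
#'   dendrogram order.
#' @method autoplot tme_report
#' @export
autoplot.tme_report <- function(object, ...) {
  ord <- object$clustering$tree$labels[object$clustering$tree$order]
  autoplot(object$scores, order_samples = ord)
}

#' Signed fold changes of a differential analysis
#'
#' One point per feature and contrast, on a log2 axis, filled by
#' significance (omnibus q below the FDR level and post-hoc p < 0.05).
#'
#' @param object A `diff_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diff_result
#' @export
autoplot.diff_result <- function(object, ...) {
  d <- as_tibble(object)
  d$contrast <- paste(d$group_a, "vs", d$group_b)
  d$log2_fc <- sign(d$fc) * log2(abs(d$fc))
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, .data$feature,
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "log2 fold change", y = NULL,
                  colour = "significant") +
    ggplot2::theme_minimal()
}
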