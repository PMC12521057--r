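# ggplot2 graphics for cohort tables and comparison objects.

#' Box plots of GN metrics across a cohort
#'
#' One box per metric; an optional dashed horizontal line marks the CMS
#' noise threshold of the exam category.
#'
#' @param cohort Exams-by-metrics data frame (see [gn_cohort_table()]).
#' @param category Optional CMS category whose threshold is drawn.
#' @param thresholds Threshold table, see [cms_thresholds()].
#' @return A ggplot object.
#' @export
plot_gn_box <- function(cohort, category = NULL, thresholds = cms_thresholds()) {
  cols <- metric_columns(as.data.frame(cohort))
  long <- tidyr::pivot_longer(as.data.frame(cohort)[cols],
                              dplyr::all_of(cols),
                              names_to = "metric", values_to = "gn_hu")
  long$metric <- factor(long$metric, levels = gn_metric_names())
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$gn_hu)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "Global noise (HU)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (!is.null(category)) {
    thr <- thresholds$noise_threshold_hu[thresholds$category == category]
    if (length(thr) == 1) {
      p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
    }
  }
  p
}

#' Correlation heatmap of GN metrics
#'
#' @param correlation A `"gn_correlation"` from
#'   [pearson_matrix_with_strength()] or a `"gn_comparison"`.
#' @return A ggplot object.
#' @export
plot_gn_heatmap <- function(correlation) {
  if (inherits(correlation, "gn_comparison")) correlation <- correlation$pearson
  stopifnot(inherits(correlation, "gn_correlation"))
  r <- correlation$r
  df <- tidyr::expand_grid(metric_a = rownames(r), metric_b = colnames(r))
  df$r <- as.vector(t(r))
  df$metric_a <- factor(df$metric_a, levels = rownames(r))
  df$metric_b <- factor(df$metric_b, levels = rev(colnames(r)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric_a, y = .data$metric_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(0, 1), na.value = "grey70") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_gn_heatmap
#' @param object A `gn_comparison`.
#' @param ... Unused.
#' @export
autoplot.gn_comparison <- function(object, ...) plot_gn_heatmap(object)
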