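# Quick-look figures for the trial table.

#' Plot a metric's distribution by group and condition
#'
#' Violin-plus-mean display of one imitation metric across the
#' Group x Condition cells.
#'
#' @param trials Trial table.
#' @param metric Metric column name (default absolute pitch deviation).
#' @return A ggplot object.
#' @export
plot_metric_by_group <- function(trials, metric = "abs_pitch_dev_cents") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    .abort("ggplot2 is needed for plotting", "vm_missing_pkg")
  }
  df <- as.data.frame(trials)
  df <- df[!is.na(df[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data[[metric]],
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5, position = ggplot2::position_dodge(0.8)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2,
                          position = ggplot2::position_dodge(0.8),
                          ggplot2::aes(group = .data$group)) +
    ggplot2::labs(x = "Condition", y = metric, fill = "Group") +
    ggplot2::theme_minimal()
}
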