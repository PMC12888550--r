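# ggplot2 views of the three result types.

#' Plot benchmark metric distributions
#'
#' Boxplots of a metric across replicates, one panel per scenario.
#'
#' @param object A `benchmark_result`.
#' @param metric Metric column to plot (default `"fscore"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, metric = "fscore", ...) {
  records <- object$records[!object$records$failed, ]
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a rank table
#'
#' Heatmap of average ranks (lower = better) by method and metric.
#'
#' @param object A `rank_table` from [rank_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$metric, y = .data$method,
                               fill = .data$m)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$m)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#d73027", high = "#4575b4",
                                 name = "avg rank") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot selection-stability profiles
#'
#' Median selection probabilities by method and importance group.
#'
#' @param object A stability tibble from [selection_stability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_stability <- function(object, ...) {
  summ <- stability_summary(object)
  summ$group <- ifelse(summ$important, "important", "non-important")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$method, y = .data$median_p,
                               fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = "median selection probability",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
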