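#' Heatmap of a correlation table
#'
#' @param object A `cor_tbl` from [cross_correlate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cor_tbl
#' @export
autoplot.cor_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$row <- factor(df$row, levels = rev(attr(object, "row_labels")))
  df$column <- factor(df$column, levels = attr(object, "col_labels"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1),
                                  name = expression(rho)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Silhouette bar chart of a stability result
#'
#' Items ordered by consensus cluster; bars show the across-run mean
#' silhouette, filled by retention, with the stability threshold marked.
#'
#' @param object A `stability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stability_result
#' @export
autoplot.stability_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(df$consensus_cluster, -df$mean_silhouette), ]
  df$item <- factor(df$item, levels = df$item)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$mean_silhouette,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::facet_grid(~ consensus_cluster, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "mean silhouette (across runs)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Metric distributions of a model evaluation
#'
#' @param object A `model_eval`.
#' @param ... Unused.
#' @return A ggplot object with one boxplot per metric over the
#'   repetitions.
#' @method autoplot model_eval
#' @export
autoplot.model_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_rep,
                            c("balanced_accuracy", "auc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s ~ %s", object$target,
                      paste(object$predictors, collapse = " + "))) +
    ggplot2::theme_minimal()
}
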