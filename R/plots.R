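#' Heatmap of a marker/environment correlation matrix
#'
#' @param object An `mps_cor` object.
#' @param ... Unused.
#' @return A ggplot: correlation heatmap with undefined (zero-variance) pairs
#'   left blank.
#' @method autoplot mps_cor
#' @export
autoplot.mps_cor <- function(object, ...) {
  long <- tidy(object)
  labels <- colnames(object)
  long$row <- factor(long$row, levels = rev(labels))
  long$column <- factor(long$column, levels = labels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$row,
                                     fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#ffffbf",
                                  high = "#2166ac", limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(title = paste("Pearson correlations,",
                                attr(object, "cell_line"), "cell line"),
                  x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Bar plot of a mutual-information feature ranking
#'
#' @param object An `mps_ranking` object.
#' @param ... Unused.
#' @return A ggplot: markers ordered by score, retention threshold as a
#'   dashed line, retained markers highlighted.
#' @method autoplot mps_ranking
#' @export
autoplot.mps_ranking <- function(object, ...) {
  df <- as_tibble(object)
  df$marker <- factor(df$marker, levels = rev(df$marker))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$marker,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = attr(object, "tau"), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    ggplot2::labs(x = "mutual information (nats)", y = NULL,
                  fill = paste0("score > ", attr(object, "tau"))) +
    ggplot2::theme_minimal()
}

#' Bar plot of aggregated cross-condition marker importance
#'
#' @param object An `mps_importance` object.
#' @param ... Unused.
#' @return A ggplot of combined feature scores, highest first.
#' @method autoplot mps_importance
#' @export
autoplot.mps_importance <- function(object, ...) {
  df <- as_tibble(object)
  df$marker <- factor(df$marker, levels = rev(df$marker))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combined_score, y = .data$marker)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "combined feature score (sum of MI, nats)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Silhouette-vs-k scan plot
#'
#' @param scores A tibble with columns `k` and `silhouette` (as returned by
#'   [select_num_clusters()]), or the full selection result.
#' @param epsilon Comparable-score tolerance to display (default 0.01).
#' @return A ggplot of the silhouette score per candidate k.
#' @export
plot_silhouette_scan <- function(scores, epsilon = 0.01) {
  if (is.list(scores) && !is.data.frame(scores) && !is.null(scores$scores)) {
    scores <- scores$scores
  }
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_hline(yintercept = max(scores$silhouette) - epsilon,
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "global silhouette") +
    ggplot2::theme_minimal()
}
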