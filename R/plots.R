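# Convenience ggplot2 views of the three headline result types: class-mean
# bars, bootstrap box plots and the signed COG significance matrix.

#' Bar chart of per-organism class means
#'
#' @param summaries Tibble from [summarize_organism()] (possibly several
#'   organisms).
#' @param metric Which metric to show (`"KaKs"`, `"Ka"` or `"Ks"`).
#' @return A ggplot object.
#' @export
plot_class_means <- function(summaries, metric = c("KaKs", "Ka", "Ks")) {
  metric <- match.arg(metric)
  d <- summaries |>
    dplyr::filter(.data$metric == !!metric) |>
    tidyr::pivot_longer(c("mean_essential", "mean_nonessential"),
                        names_to = "class", values_to = "mean") |>
    dplyr::mutate(class = sub("mean_", "", .data$class))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$organism_id, y = .data$mean,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(essential = "#3B6FB6",
                                          nonessential = "#C23B3B")) +
    ggplot2::labs(x = NULL, y = paste("mean", metric), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Box plots of bootstrap replicate means
#'
#' @param bootstrap Long bootstrap tibble (`organism_id`, `metric`, `class`,
#'   `replicate_mean`) as written by [run_pipeline()].
#' @param metric Which metric to show.
#' @return A ggplot object.
#' @export
plot_bootstrap <- function(bootstrap, metric = c("KaKs", "Ka", "Ks")) {
  metric <- match.arg(metric)
  d <- dplyr::filter(bootstrap, .data$metric == !!metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$organism_id,
                                  y = .data$replicate_mean,
                                  fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.3, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(essential = "#3B6FB6",
                                          nonessential = "#C23B3B")) +
    ggplot2::labs(x = NULL, y = paste("bootstrap mean", metric),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Tile view of the signed COG significance matrix
#'
#' Blue tiles: essential genes significantly more conserved in that
#' (organism, category); red: the opposite; grey: no significant difference.
#'
#' @param object A `cog_matrix` from [cog_significance_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cog_matrix
#' @export
autoplot.cog_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category,
                                       y = .data$organism_id,
                                       fill = .data$direction)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(
      essential_conserved = "#3B6FB6",
      nonessential_conserved = "#C23B3B",
      none = "grey85"
    )) +
    ggplot2::labs(x = "COG category", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
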