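#' Co-occurrence index against genetic distance
#'
#' Scatter of the pair-level co-occurrence index (Spearman rho) against
#' genetic distance with a least-squares line, facetted by experiment -
#' the visual check of the environmental-filtering prediction (a negative
#' slope).
#'
#' @param pairs Pair tibble from [pair_table()].
#' @return A ggplot object.
#' @export
plot_cooccurrence_gd <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$gd, y = .data$rho)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "red",
                         se = FALSE, linewidth = 0.6) +
    ggplot2::facet_wrap(~experiment_id) +
    ggplot2::labs(x = "Genetic distance", y = "Co-occurrence index (Spearman rho)") +
    ggplot2::theme_bw()
}

#' Per-treatment alpha diversity
#'
#' @param table Wide abundance tibble of counts.
#' @param metadata Sample metadata tibble.
#' @param metric Diversity index to plot (default `"shannon"`).
#' @return A ggplot object (boxplots of per-sample diversity by treatment).
#' @export
plot_treatment_diversity <- function(table, metadata, metric = "shannon") {
  div <- sample_diversity(table) |>
    dplyr::left_join(metadata, by = "sample_id")
  ggplot2::ggplot(div, ggplot2::aes(x = .data$treatment_id, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Treatment", y = metric) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot cooc_network
#' @export
autoplot.cooc_network <- function(object, ...) {
  long <- degree_by_taxon(object) |>
    tidyr::pivot_longer(c("degree", "pos_degree", "neg_degree"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Edges per node") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot cooc_glm
#' @export
autoplot.cooc_glm <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error
    )) +
    ggplot2::labs(x = "Estimate (normalised scale)", y = NULL) +
    ggplot2::theme_bw()
}
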