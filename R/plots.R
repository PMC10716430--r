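#' Boxplots of a per-sample metric across biomes, annotated with letters
#'
#' The standard presentation for between-biome comparisons: boxes per biome
#' with the compact letter display from [group_compare()] above them.
#'
#' @param data tibble of per-sample profiles.
#' @param value metric column name (e.g. `"delta_nrfa_nir"` or
#'   `"nrfA_per_gbp"`).
#' @param group grouping column name (e.g. `"biome"`).
#' @param alpha significance level passed to [group_compare()].
#' @return a ggplot.
#' @export
plot_group_metric <- function(data, value = "delta_nrfa_nir", group = "biome",
                              alpha = 0.05) {
  cmp <- group_compare(data, value, group, alpha = alpha)
  ann <- cmp$groups
  ymax <- max(data[[value]], na.rm = TRUE)
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]], y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_text(data = ann,
                       ggplot2::aes(x = .data$group, y = ymax * 1.08,
                                    label = .data$letters),
                       inherit.aes = FALSE, size = 3.2) +
    ggplot2::labs(x = NULL, y = value,
                  subtitle = sprintf("Kruskal-Wallis H(%d) = %.1f, p = %.3g",
                                     cmp$df, cmp$statistic, cmp$p.value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' @method autoplot nitro_ale
#' @export
autoplot.nitro_ale <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (is.numeric(d$x)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$effect)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = d$feature[1], y = "Accumulated local effect") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$effect)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_col() +
      ggplot2::labs(x = d$feature[1], y = "Accumulated local effect") +
      ggplot2::theme_minimal()
  }
}

#' @method autoplot nitro_edgepca
#' @export
autoplot.nitro_edgepca <- function(object, mapping = NULL, ...) {
  d <- object$projections
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)",
                  100 * object$eigenvalues[1] / sum(object$eigenvalues)),
      y = sprintf("PC2 (%.0f%%)",
                  100 * object$eigenvalues[2] / sum(object$eigenvalues))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
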