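# ggplot2 displays for the main result types

#' Plot per-group divergence distributions
#'
#' Boxplots of the per-tree minimum normalized root-to-tip distances, one
#' box per group, ordered by increasing mean (least-diverged groups first —
#' the candidates for the earliest split).
#'
#' @param records Output of [group_divergence()] for a single metric.
#' @return A ggplot object.
#' @export
plot_divergence <- function(records) {
  check_columns(records, c("group", "normalized_distance"), "records")
  ord <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$normalized_distance), .groups = "drop") |>
    dplyr::arrange(.data$m)
  records |>
    dplyr::mutate(group = factor(.data$group, levels = ord$group)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group,
                                 y = .data$normalized_distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "normalized root-to-tip distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-group sister-diversity distributions
#'
#' @param records A data frame with columns `group`, `score` (stack
#'   [sister_diversity()] results over trees).
#' @return A ggplot object (groups ordered by decreasing mean score; the
#'   most ancestral-looking group first).
#' @export
plot_sister_diversity <- function(records) {
  check_columns(records, c("group", "score"), "records")
  ord <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(m = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m))
  records |>
    dplyr::mutate(group = factor(.data$group, levels = ord$group)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "sister-clade diversity score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heatmap of the pairwise divergence-test matrix
#'
#' Tile plot of the asymmetric one-sided p-value matrix; significant cells
#' (after Bonferroni correction) are outlined.
#'
#' @param object A [pairwise_divergence_tests()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pairwise_wilcoxon <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$group_b, y = .data$group_a,
                                 fill = log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = function(d) dplyr::filter(d, .data$significant),
      fill = NA, colour = "black", linewidth = 0.6
    ) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "group b (more diverged under H1)",
                  y = "group a (less diverged under H1)",
                  fill = "log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
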