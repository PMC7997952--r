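# broom-style tidy()/glance() methods for the package's result objects

#' Tidy a MAD root inference
#'
#' @param x A [mad_root()] object.
#' @param ... Unused.
#' @return The per-branch candidate table (best branch first).
#' @export
tidy.mad_root <- function(x, ...) x$table

#' One-row summary of a MAD root inference
#'
#' @param x A [mad_root()] object.
#' @param ... Unused.
#' @return A one-row tibble with the best branch, position, MAD value,
#'   ambiguity index and ambiguity flag.
#' @export
glance.mad_root <- function(x, ...) {
  tibble(
    best_edge = x$best_edge,
    best_position = x$best_position,
    mad_value = x$mad_value,
    ambiguity_index = x$ambiguity_index,
    is_ambiguous = x$is_ambiguous,
    n_branches = nrow(x$table)
  )
}

#' Tidy a network reduction result
#'
#' @param x A [reduce_network()] result.
#' @param ... Unused.
#' @return One row per candidate reaction with its score, whether it was
#'   retained, and (for removed reactions) the removal step and pass.
#' @export
tidy.reduction_result <- function(x, ...) {
  dplyr::bind_rows(
    x$retained |>
      dplyr::transmute(.data$reaction_id, .data$score, retained = TRUE,
                       step = NA_integer_, pass = NA_integer_),
    x$removed |>
      dplyr::transmute(.data$reaction_id, .data$score, retained = FALSE,
                       .data$step, .data$pass)
  ) |>
    dplyr::arrange(.data$retained, .data$step)
}

#' One-row summary of a network reduction
#'
#' @param x A [reduce_network()] result.
#' @param ... Unused.
#' @return A one-row tibble with candidate counts, pass count, target
#'   producibility before/after and the 1-minimality flag.
#' @export
glance.reduction_result <- function(x, ...) {
  tibble(
    n_retained = nrow(x$retained),
    n_removed = nrow(x$removed),
    n_passes = x$n_passes,
    targets_producible_before = sum(x$producible_before$producible),
    targets_producible_after = sum(x$producible_after$producible),
    n_targets = nrow(x$producible_after),
    minimal = x$minimal
  )
}

#' Tidy a pairwise Wilcoxon test matrix
#'
#' @param x A [pairwise_divergence_tests()] result.
#' @param ... Unused.
#' @return A long tibble with one row per ordered group pair: `group_a`,
#'   `group_b`, `p_value`, `p_adjusted` (Bonferroni), `significant`,
#'   `n_shared_trees`.
#' @export
tidy.pairwise_wilcoxon <- function(x, ...) {
  long <- as_tibble(as.data.frame(as.table(x$p), stringsAsFactors = FALSE))
  names(long) <- c("group_a", "group_b", "p_value")
  long |>
    dplyr::filter(.data$group_a != .data$group_b) |>
    dplyr::mutate(
      p_adjusted = pmin(.data$p_value * x$multiplier, 1),
      significant = .data$p_adjusted < x$alpha,
      n_shared_trees = x$n_shared[cbind(.data$group_a, .data$group_b)]
    ) |>
    dplyr::arrange(.data$group_a, .data$group_b)
}

#' One-row summary of a pairwise Wilcoxon test matrix
#'
#' @param x A [pairwise_divergence_tests()] result.
#' @param ... Unused.
#' @return A one-row tibble with the group count, tested pair count,
#'   significance level and number of significant cells.
#' @export
glance.pairwise_wilcoxon <- function(x, ...) {
  tibble(
    n_groups = length(x$groups),
    n_pairs = x$multiplier,
    alpha = x$alpha,
    n_significant = sum(x$significant, na.rm = TRUE)
  )
}
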