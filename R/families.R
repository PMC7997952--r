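#' Build a thresholded protein similarity graph
#'
#' Turns a table of pairwise global identities into a weighted undirected
#' graph. Edges are kept when `global_identity >= min_identity` (percent)
#' and `e_value <= max_e`; edge weight is the global identity. Duplicate
#' pairs (in either orientation) are collapsed keeping the maximum identity.
#' Every sequence seen in the table becomes a node even if all of its edges
#' are filtered out.
#'
#' @param edges A data frame with columns `seq_a`, `seq_b`, `global_identity`
#'   (percent in \[0, 100\]) and `e_value`.
#' @param min_identity Minimum global identity (percent), inclusive. Default 25.
#' @param max_e Maximum e-value, inclusive. Default 1e-10.
#'
#' @return An [igraph][igraph::graph_from_data_frame] undirected graph with a
#'   `weight` edge attribute.
#' @export
build_similarity_graph <- function(edges, min_identity = 25, max_e = 1e-10) {
  check_columns(edges, c("seq_a", "seq_b", "global_identity", "e_value"),
                "edges")
  bad <- which(edges$global_identity < 0 | edges$global_identity > 100 |
                 !is.finite(edges$global_identity))
  if (length(bad) > 0) {
    abort(c("global_identity outside [0, 100]:",
            sprintf("row(s) %s", paste(head(bad, 10), collapse = ", "))))
  }
  if (any(edges$e_value < 0)) abort("e_value must be non-negative")
  self <- which(edges$seq_a == edges$seq_b)
  if (length(self) > 0) {
    abort(c("self-edges (seq_a == seq_b) are not allowed:",
            sprintf("row(s) %s", paste(head(self, 10), collapse = ", "))))
  }
  nodes <- unique(c(as.character(edges$seq_a), as.character(edges$seq_b)))
  kept <- edges |>
    dplyr::filter(.data$global_identity >= min_identity,
                  .data$e_value <= max_e)
  kept <- dplyr::bind_cols(
    canonical_pair(as.character(kept$seq_a), as.character(kept$seq_b)),
    weight = kept$global_identity
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight)) |>
    dplyr::distinct(.data$seq_a, .data$seq_b, .keep_all = TRUE)
  igraph::graph_from_data_frame(
    kept,
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
}

#' Cluster a similarity graph into protein families with MCL
#'
#' Markov clustering on the weighted graph: a column-stochastic transition
#' matrix is formed from the edge weights after adding a self-loop to each
#' node (weight equal to its maximum incident edge weight, or 1 for isolated
#' nodes), then expansion (matrix squaring) and inflation (entrywise power
#' followed by column renormalization) alternate until the matrix changes by
#' less than `tol` or `max_iter` iterations elapse. Families are the
#' connected components of the converged attractor matrix. The procedure is
#' deterministic given the input graph.
#'
#' @param graph A weighted undirected igraph, e.g. from
#'   [build_similarity_graph()].
#' @param inflation Inflation exponent, must exceed 1. Default 2.
#' @param max_iter Maximum number of expansion/inflation rounds. Default 100.
#' @param tol Convergence tolerance on the maximum entrywise change.
#'   Default 1e-6.
#'
#' @return A tibble with columns `family_id`, `sequence_id`; one row per
#'   sequence, each sequence in exactly one family. Families are numbered by
#'   decreasing size (ties by smallest member name). The attribute
#'   `converged` records whether the iteration reached `tol`; a warning is
#'   raised otherwise and the current partition returned.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100, tol = 1e-6) {
  if (!igraph::is_igraph(graph)) abort("`graph` must be an igraph object")
  if (inflation <= 1) abort("`inflation` must be > 1")
  n <- igraph::vcount(graph)
  if (n == 0) {
    out <- tibble(family_id = character(), sequence_id = character())
    attr(out, "converged") <- TRUE
    return(out)
  }
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph) > 0 &&
                                                     "weight" %in% igraph::edge_attr_names(graph))
                                                  "weight" else NULL,
                                   sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix") * 1.0
  # self-loops: max incident weight, 1 for isolated nodes
  maxw <- apply(A, 2, function(col) if (any(col > 0)) max(col) else 1)
  Matrix::diag(A) <- maxw
  normalize_cols <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize_cols(A)
  converged <- FALSE
  prune <- 1e-12
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation (entrywise power)
    M2 <- Matrix::drop0(M2, tol = prune)
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("MCL did not converge within `max_iter`; returning current partition")
  }
  # attractor components: symmetrize the non-zero pattern and take components
  S <- Matrix::drop0(M, tol = 1e-7)
  S <- (S + Matrix::t(S)) > 0
  g2 <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(g2)$membership
  clusters <- split(nodes, comp)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(x) min(x), character(1)))
  clusters <- clusters[ord]
  out <- tibble(
    family_id = rep(sprintf("F%05d", seq_along(clusters)), lengths(clusters)),
    sequence_id = unlist(clusters, use.names = FALSE)
  )
  attr(out, "converged") <- converged
  out
}

#' Filter families by species/genome support and tabulate group presence
#'
#' Removes families observed in fewer than `min_species` distinct species or
#' fewer than `min_genomes` distinct genomes, then tabulates, for every
#' retained family and every taxonomic group, how many of the group's genomes
#' carry at least one member sequence.
#'
#' @param families A data frame with columns `family_id`, `sequence_id`,
#'   `genome_id`.
#' @param genomes Genome metadata with columns `genome_id`, `species`,
#'   `group` (e.g. from [assign_groups()]). Every member genome must appear
#'   here, otherwise an error names the missing genomes.
#' @param min_species,min_genomes Inclusive support thresholds. Defaults 3
#'   and 4.
#'
#' @return A list with elements `families` (the retained membership tibble)
#'   and `presence`, a tibble with columns `family_id`, `group`,
#'   `genomes_with_family`, `genomes_in_group` covering every retained family
#'   crossed with every group present in `genomes`.
#' @export
filter_families <- function(families, genomes, min_species = 3,
                            min_genomes = 4) {
  check_columns(families, c("family_id", "sequence_id", "genome_id"),
                "families")
  check_columns(genomes, c("genome_id", "species", "group"), "genomes")
  unknown <- setdiff(unique(families$genome_id), genomes$genome_id)
  if (length(unknown) > 0) {
    abort(c("family members reference genomes without a group mapping:",
            paste(head(unknown, 10), collapse = ", ")))
  }
  meta <- dplyr::distinct(genomes, .data$genome_id, .data$species, .data$group)
  fam <- dplyr::left_join(as_tibble(families), meta, by = "genome_id")
  support <- fam |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(n_species = dplyr::n_distinct(.data$species),
                     n_genomes = dplyr::n_distinct(.data$genome_id),
                     .groups = "drop")
  keep <- support |>
    dplyr::filter(.data$n_species >= min_species,
                  .data$n_genomes >= min_genomes) |>
    dplyr::pull("family_id")
  fam_kept <- dplyr::filter(fam, .data$family_id %in% keep)
  group_sizes <- meta |>
    dplyr::count(.data$group, name = "genomes_in_group")
  presence <- fam_kept |>
    dplyr::distinct(.data$family_id, .data$group, .data$genome_id) |>
    dplyr::count(.data$family_id, .data$group, name = "genomes_with_family") |>
    tidyr::complete(family_id = keep, group = group_sizes$group,
                    fill = list(genomes_with_family = 0L)) |>
    dplyr::left_join(group_sizes, by = "group") |>
    dplyr::arrange(.data$family_id, .data$group)
  list(
    families = dplyr::select(fam_kept, "family_id", "sequence_id",
                             "genome_id"),
    presence = presence
  )
}

#' Universality and mean group coverage of protein families
#'
#' A family is universal when it has at least one member genome in every
#' taxonomic group of the presence table. Mean coverage is the unweighted
#' mean, over groups, of the fraction of the group's genomes carrying the
#' family.
#'
#' @param presence A presence tibble as produced by [filter_families()], with
#'   columns `family_id`, `group`, `genomes_with_family`, `genomes_in_group`.
#' @param coverage_threshold Coverage level of interest; the returned
#'   `high_coverage` column flags universal families whose mean coverage
#'   reaches it. Default 0.9.
#'
#' @return A tibble with one row per family: `family_id`,
#'   `n_groups_present`, `mean_coverage`, `universal`, `high_coverage`.
#' @export
universal_families <- function(presence, coverage_threshold = 0.9) {
  check_columns(presence, c("family_id", "group", "genomes_with_family",
                            "genomes_in_group"), "presence")
  if (nrow(presence) == 0) abort("`presence` is empty")
  if (any(presence$genomes_in_group <= 0)) {
    abort("every group must contain at least one genome")
  }
  n_groups <- dplyr::n_distinct(presence$group)
  presence |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_groups_present = sum(.data$genomes_with_family >= 1),
      mean_coverage = mean(.data$genomes_with_family /
                             .data$genomes_in_group),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      universal = .data$n_groups_present == n_groups,
      high_coverage = .data$universal &
        .data$mean_coverage >= coverage_threshold
    )
}

#' Annotate families by majority vote over best per-sequence hits
#'
#' For every sequence the best passing hit is kept (hits must satisfy
#' `query_coverage >= min_qcov`, `e_value <= max_e` and a length ratio inside
#' `ratio_bounds`; the best hit is the one with lowest e-value, ties broken
#' by higher coverage, then higher identity, then lexicographic subject id).
#' Each family is then annotated with the most frequent category among its
#' annotated members; on frequency ties all tied categories are returned.
#'
#' @param families A data frame with columns `family_id`, `sequence_id`.
#' @param hits Per-sequence hits with columns `query_id` (matching
#'   `sequence_id`), `subject_id`, `e_value`, `query_coverage` (fraction),
#'   `percent_identity`, `length_ratio`, `category`.
#' @param min_qcov Minimum query coverage (fraction). Default 0.8.
#' @param max_e Maximum e-value. Default 1e-10.
#' @param ratio_bounds Inclusive bounds on the query/subject length ratio.
#'   Default `c(0.7, 1.3)`.
#'
#' @return A tibble with columns `family_id`, `category`, `n_members`
#'   (number of annotated members supporting the category); families whose
#'   members have no passing hits are absent.
#' @export
annotate_families <- function(families, hits, min_qcov = 0.8, max_e = 1e-10,
                              ratio_bounds = c(0.7, 1.3)) {
  check_columns(families, c("family_id", "sequence_id"), "families")
  check_columns(hits, c("query_id", "subject_id", "e_value",
                        "query_coverage", "percent_identity", "length_ratio",
                        "category"), "hits")
  best <- hits |>
    dplyr::filter(.data$query_coverage >= min_qcov,
                  .data$e_value <= max_e,
                  .data$length_ratio >= ratio_bounds[1],
                  .data$length_ratio <= ratio_bounds[2]) |>
    dplyr::arrange(.data$query_id, .data$e_value,
                   dplyr::desc(.data$query_coverage),
                   dplyr::desc(.data$percent_identity), .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  as_tibble(families) |>
    dplyr::inner_join(best, by = c(sequence_id = "query_id")) |>
    dplyr::count(.data$family_id, .data$category, name = "n_members") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::slice_max(.data$n_members, with_ties = TRUE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$family_id, .data$category)
}
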