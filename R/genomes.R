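#' Classify genomes by oxygen usage and retain anaerobes
#'
#' Classifies each genome as aerobic or anaerobic from its homology hits
#' against a reference set of heme-copper oxygen reductases (HCO) and nitric
#' oxide reductases (NOR), then retains the anaerobic genomes with more than
#' `min_proteins` protein sequences (small proteomes are excluded as likely
#' energy parasites).
#'
#' A genome is called aerobic when it has at least one hit with identity
#' strictly above `min_identity`, e-value strictly below `max_e` and an
#' aligned length of at least `min_aligned` amino acids. All other genomes
#' are anaerobic.
#'
#' @param genomes A data frame with columns `genome_id`, `protein_count`
#'   (additional columns such as `phylum`, `class_name`, `species` are kept).
#' @param hits A data frame of hits against the HCO/NOR reference set with
#'   columns `genome_id`, `percent_identity`, `e_value`, `aligned_length_aa`.
#'   A hit referencing a `genome_id` absent from `genomes` is an error.
#' @param min_proteins Minimum proteome size; genomes with
#'   `protein_count > min_proteins` are retained. Default 1000.
#' @param min_identity,max_e,min_aligned Oxygen-classification thresholds:
#'   identity > 25 (percent), e-value < 1e-10, aligned length >= 300 aa.
#'
#' @return A tibble of the retained (anaerobic, large-proteome) genomes in
#'   input order, with an added `oxygen_class` column.
#' @export
#' @examples
#' genomes <- tibble::tibble(
#'   genome_id = c("g1", "g2"), phylum = "Firmicutes",
#'   protein_count = c(1500L, 2000L)
#' )
#' hits <- tibble::tibble(
#'   genome_id = "g2", percent_identity = 40,
#'   e_value = 1e-30, aligned_length_aa = 500L
#' )
#' select_anaerobes(genomes, hits) # g1 kept, g2 aerobic
select_anaerobes <- function(genomes, hits, min_proteins = 1000,
                             min_identity = 25, max_e = 1e-10,
                             min_aligned = 300) {
  check_columns(genomes, c("genome_id", "protein_count"), "genomes")
  check_columns(hits, c("genome_id", "percent_identity", "e_value",
                        "aligned_length_aa"), "hits")
  unknown <- setdiff(unique(hits$genome_id), genomes$genome_id)
  if (length(unknown) > 0) {
    abort(c("hits reference genome ids absent from `genomes`:",
            paste(head(unknown, 10), collapse = ", ")))
  }
  if (any(hits$e_value < 0) ||
      any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    abort("hits must have e_value >= 0 and percent_identity in [0, 100]")
  }
  aerobic_ids <- hits |>
    dplyr::filter(.data$percent_identity > min_identity,
                  .data$e_value < max_e,
                  .data$aligned_length_aa >= min_aligned) |>
    dplyr::pull("genome_id") |>
    unique()
  genomes |>
    as_tibble() |>
    dplyr::mutate(oxygen_class = ifelse(.data$genome_id %in% aerobic_ids,
                                        "aerobic", "anaerobic")) |>
    dplyr::filter(.data$oxygen_class == "anaerobic",
                  .data$protein_count > min_proteins)
}

#' Assign genomes to major taxonomic groups
#'
#' Maps each genome to its analysis group: Firmicutes and Proteobacteria
#' genomes are split into their classes (these phyla dwarf the others in
#' representation), any other phylum with at least `min_species` distinct
#' species keeps its phylum label, and the remaining phyla are pooled into
#' the residual `"Other Bacteria"` bin.
#'
#' @param genomes A data frame with columns `genome_id`, `phylum`, `species`;
#'   `class_name` is required for Firmicutes and Proteobacteria genomes.
#' @param min_species Minimum number of distinct species for a phylum to keep
#'   its own label. Default 5.
#' @param split_phyla Phyla resolved at class level. Default
#'   `c("Firmicutes", "Proteobacteria")`.
#'
#' @return The input tibble with an added `group` column.
#' @export
assign_groups <- function(genomes, min_species = 5,
                          split_phyla = c("Firmicutes", "Proteobacteria")) {
  check_columns(genomes, c("genome_id", "phylum", "species"), "genomes")
  genomes <- as_tibble(genomes)
  needs_class <- genomes$phylum %in% split_phyla
  if (any(needs_class)) {
    cls <- if ("class_name" %in% names(genomes)) genomes$class_name else
      rep(NA_character_, nrow(genomes))
    bad <- needs_class & (is.na(cls) | cls == "")
    if (any(bad)) {
      abort(c("class-level phyla require a non-empty `class_name`:",
              paste(head(genomes$genome_id[bad], 10), collapse = ", ")))
    }
  }
  species_per_phylum <- genomes |>
    dplyr::distinct(.data$phylum, .data$species) |>
    dplyr::count(.data$phylum, name = "n_species")
  genomes |>
    dplyr::left_join(species_per_phylum, by = "phylum") |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$phylum %in% split_phyla ~ .data$class_name,
        .data$n_species >= min_species ~ .data$phylum,
        TRUE ~ "Other Bacteria"
      )
    ) |>
    dplyr::select(-"n_species")
}
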