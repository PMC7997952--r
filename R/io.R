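# Tab-separated readers/writers for the pipeline's tabular artifacts.
# All files are UTF-8 TSV with a header row; trees travel as Newick via ape.

#' Read and write pipeline tables
#'
#' Thin, validating wrappers around [readr::read_tsv()] /
#' [readr::write_tsv()] for the tables the pipeline exchanges: genome
#' metadata (`genome_id`, `phylum`, `class_name`, `species`,
#' `protein_count`), similarity edges (`seq_a`, `seq_b`, `global_identity`,
#' `e_value`), family membership (`family_id`, `sequence_id`, `genome_id`),
#' presence matrices and reaction tables (`reaction_id`, `equation`, and
#' optionally a semicolon-separated `kos` column). `write_tsv` serializes
#' doubles with shortest round-trip precision, so numeric columns survive a
#' write/read cycle exactly.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `x` invisibly.
#' @name pipeline_io
NULL

read_checked <- function(path, required) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(x, required, path)
  x
}

#' @rdname pipeline_io
#' @export
read_genome_table <- function(path) {
  read_checked(path, c("genome_id", "phylum", "species", "protein_count"))
}

#' @rdname pipeline_io
#' @export
read_edge_table <- function(path) {
  read_checked(path, c("seq_a", "seq_b", "global_identity", "e_value"))
}

#' @rdname pipeline_io
#' @export
write_edge_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_family_table <- function(path) {
  read_checked(path, c("family_id", "sequence_id", "genome_id"))
}

#' @rdname pipeline_io
#' @export
write_family_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_presence_table <- function(path) {
  read_checked(path, c("family_id", "group", "genomes_with_family",
                       "genomes_in_group"))
}

#' @rdname pipeline_io
#' @export
write_presence_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname pipeline_io
#' @export
read_reaction_table <- function(path) {
  read_checked(path, c("reaction_id", "equation"))
}

#' @rdname pipeline_io
#' @export
write_reaction_table <- function(x, path) {
  out <- x[, intersect(c("reaction_id", "equation", "reversible", "kos"),
                       names(x))]
  readr::write_tsv(out, path)
  invisible(x)
}

#' Export the bipartite network as an edge-list table or GraphML
#'
#' @param network A network list from [build_reaction_network()].
#' @param path Output file path.
#' @param format `"tsv"` (edge list with `from`, `to`) or `"graphml"`.
#' @return The network, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    el <- igraph::as_data_frame(network$graph, what = "edges")
    readr::write_tsv(as_tibble(el), path)
  } else {
    igraph::write_graph(network$graph, path, format = "graphml")
  }
  invisible(network)
}
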