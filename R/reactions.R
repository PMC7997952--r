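# KEGG-style reaction parsing and the bipartite metabolite-reaction network.
# A parsed reaction set is a tibble with one row per reaction and list-columns
# `substrates` / `products` holding named integer coefficient vectors.

compound_id_ok <- function(x) grepl("^[A-Za-z][A-Za-z0-9_]*$", x)

parse_side <- function(side, side_name) {
  side <- trimws(side)
  if (side == "") {
    return(list(error = "empty side", position = side_name))
  }
  if (grepl("^\\+|\\+\\s*\\+|\\+$", side)) {
    return(list(error = "malformed term", position = side_name))
  }
  terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
  terms <- terms[terms != ""]
  if (length(terms) == 0) {
    return(list(error = "empty side", position = side_name))
  }
  coefs <- integer(0)
  for (i in seq_along(terms)) {
    tok <- strsplit(trimws(terms[i]), "\\s+")[[1]]
    pos <- sprintf("%s term %d", side_name, i)
    if (length(tok) == 1) {
      cf <- 1L
      cmp <- tok[1]
    } else if (length(tok) == 2) {
      if (grepl("[nm]", tok[1])) {
        return(list(error = "ambiguous stoichiometry", position = pos))
      }
      if (!grepl("^[0-9]+$", tok[1])) {
        return(list(error = "malformed coefficient", position = pos))
      }
      cf <- as.integer(tok[1])
      if (cf <= 0L) {
        return(list(error = "malformed coefficient", position = pos))
      }
      cmp <- tok[2]
    } else {
      return(list(error = "malformed term", position = pos))
    }
    if (!compound_id_ok(cmp)) {
      return(list(error = "unknown compound", position = pos))
    }
    coefs[cmp] <- (if (cmp %in% names(coefs)) coefs[[cmp]] else 0L) + cf
  }
  list(coefs = coefs)
}

#' Parse KEGG-style reaction equations
#'
#' Parses equations of the dialect `"a C00001 + b C00002 <=> c C00003"`
#' (coefficients optional and defaulting to 1, separator `<=>` or `=>`).
#' Reactions are rejected, with a reason and the position of failure, when a
#' coefficient contains the symbolic characters `n` or `m` (ambiguous
#' stoichiometry), a compound token is not a well-formed identifier, the
#' syntax is malformed, or (by default) the same compound occurs on both
#' sides with an identical coefficient (a transport-like equation).
#'
#' @param reactions A data frame with columns `reaction_id`, `equation`.
#' @param allow_transport Keep reactions having a compound on both sides with
#'   the same coefficient. Default `FALSE` (rejected).
#'
#' @return A list with `reactions`, a tibble with columns `reaction_id`,
#'   `substrates` (list of named integer vectors), `products`, `reversible`
#'   (all `FALSE` at parse time; see [assign_reversibility()]) and `equation`
#'   (the canonical re-serialized form); and `rejected`, a tibble with
#'   columns `reaction_id`, `reason`, `position`.
#' @export
#' @examples
#' parse_reactions(tibble::tibble(
#'   reaction_id = c("R1", "R2"),
#'   equation = c("C1 + 2 C2 <=> C3", "n C1 <=> C2")
#' ))
parse_reactions <- function(reactions, allow_transport = FALSE) {
  check_columns(reactions, c("reaction_id", "equation"), "reactions")
  ok <- list()
  rej <- list()
  for (i in seq_len(nrow(reactions))) {
    id <- as.character(reactions$reaction_id[i])
    eq <- as.character(reactions$equation[i])
    sep <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
      if (grepl("=>", eq, fixed = TRUE)) "=>" else NA_character_
    if (is.na(sep)) {
      rej[[length(rej) + 1]] <- tibble(reaction_id = id,
                                       reason = "malformed equation",
                                       position = "missing separator")
      next
    }
    sides <- strsplit(eq, sep, fixed = TRUE)[[1]]
    if (length(sides) != 2) {
      rej[[length(rej) + 1]] <- tibble(reaction_id = id,
                                       reason = "malformed equation",
                                       position = "multiple separators")
      next
    }
    lhs <- parse_side(sides[1], "lhs")
    rhs <- if (is.null(lhs$error)) parse_side(sides[2], "rhs") else NULL
    bad <- if (!is.null(lhs$error)) lhs else
      if (!is.null(rhs$error)) rhs else NULL
    if (!is.null(bad)) {
      rej[[length(rej) + 1]] <- tibble(reaction_id = id, reason = bad$error,
                                       position = bad$position)
      next
    }
    shared <- intersect(names(lhs$coefs), names(rhs$coefs))
    if (!allow_transport && length(shared) > 0 &&
        any(lhs$coefs[shared] == rhs$coefs[shared])) {
      rej[[length(rej) + 1]] <- tibble(
        reaction_id = id, reason = "transport-like equation",
        position = paste(shared[lhs$coefs[shared] == rhs$coefs[shared]],
                         collapse = ", ")
      )
      next
    }
    ok[[length(ok) + 1]] <- tibble(
      reaction_id = id,
      substrates = list(lhs$coefs),
      products = list(rhs$coefs),
      reversible = FALSE
    )
  }
  parsed <- if (length(ok) > 0) dplyr::bind_rows(ok) else
    tibble(reaction_id = character(), substrates = list(),
           products = list(), reversible = logical())
  parsed$equation <- format_reaction(parsed)
  list(
    reactions = parsed,
    rejected = if (length(rej) > 0) dplyr::bind_rows(rej) else
      tibble(reaction_id = character(), reason = character(),
             position = character())
  )
}

#' Serialize parsed reactions back to canonical equation strings
#'
#' Inverse of [parse_reactions()]: coefficients of 1 are omitted, compounds
#' appear in their stored order, and the separator reflects reversibility
#' (`<=>` for reversible, `=>` otherwise).
#'
#' @param reactions A parsed reaction tibble.
#' @return A character vector of equations, one per reaction.
#' @export
format_reaction <- function(reactions) {
  fmt_side <- function(coefs) {
    paste(ifelse(coefs == 1L, names(coefs),
                 paste(coefs, names(coefs))), collapse = " + ")
  }
  vapply(seq_len(nrow(reactions)), function(i) {
    sep <- if (isTRUE(reactions$reversible[i])) "<=>" else "=>"
    paste(fmt_side(reactions$substrates[[i]]), sep,
          fmt_side(reactions$products[[i]]))
  }, character(1))
}

#' Assign reaction reversibility from a lookup table
#'
#' Reactions present in the table take its value; reactions absent from the
#' table are irreversible (the convention for reactions never observed in a
#' pathway-map file).
#'
#' @param reactions A parsed reaction tibble.
#' @param reversibility A data frame with columns `reaction_id`,
#'   `reversible` (logical), or `NULL`/empty for all-irreversible.
#' @return The reaction tibble with its `reversible` column (and canonical
#'   `equation`) updated.
#' @export
assign_reversibility <- function(reactions, reversibility = NULL) {
  rev_map <- if (is.null(reversibility) || nrow(reversibility) == 0) {
    logical(0)
  } else {
    check_columns(reversibility, c("reaction_id", "reversible"),
                  "reversibility")
    setNames(as.logical(reversibility$reversible),
             as.character(reversibility$reaction_id))
  }
  hit <- unname(rev_map[reactions$reaction_id])
  reactions$reversible <- !is.na(hit) & hit
  reactions$equation <- format_reaction(reactions)
  reactions
}

#' Map protein families to reactions through KO annotations
#'
#' Joins family KO annotations to the KO-to-reaction reference table, taking
#' the union over a family's KOs. KOs without any associated reaction are
#' silently ignored but counted in the returned summary.
#'
#' @param family_kos A data frame with columns `family_id`, `ko`.
#' @param ko_reactions A data frame with columns `ko`, `reaction_id`.
#' @param reactions Optionally, a parsed reaction tibble whose
#'   `encoding_families` list-column should be filled.
#'
#' @return A list with `map` (tibble `family_id`, `reaction_id`, distinct
#'   pairs), `reactions` (the input tibble with an `encoding_families`
#'   list-column, or `NULL`), and `unmapped_kos` (KOs lacking any reaction).
#' @export
families_to_reactions <- function(family_kos, ko_reactions,
                                  reactions = NULL) {
  check_columns(family_kos, c("family_id", "ko"), "family_kos")
  check_columns(ko_reactions, c("ko", "reaction_id"), "ko_reactions")
  map <- as_tibble(family_kos) |>
    dplyr::inner_join(as_tibble(ko_reactions), by = "ko",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$family_id, .data$reaction_id) |>
    dplyr::arrange(.data$family_id, .data$reaction_id)
  unmapped <- setdiff(unique(family_kos$ko), unique(ko_reactions$ko))
  if (!is.null(reactions)) {
    fams_by_rxn <- split(map$family_id, map$reaction_id)
    reactions$encoding_families <- lapply(reactions$reaction_id, function(id) {
      sort(unique(fams_by_rxn[[id]] %||% character(0)))
    })
  }
  list(map = map, reactions = reactions, unmapped_kos = unmapped)
}

#' Build the bipartite metabolite-reaction network
#'
#' Constructs a directed bipartite graph with an edge from every substrate to
#' its reaction and from every reaction to its products; reversible reactions
#' carry edges in both orientations. Node degrees and connected components
#' are computed on the undirected simplified skeleton (the connectivity
#' notion used when asking whether a reaction is disconnected from the rest
#' of the network).
#'
#' @param reactions A parsed reaction tibble, deduplicated by `reaction_id`.
#' @return A list with `graph` (a directed igraph whose vertices carry a
#'   `kind` attribute, `"metabolite"` or `"reaction"`), `nodes` (tibble with
#'   `name`, `kind`, `degree`, `component`; components numbered by
#'   decreasing size) and `components` (tibble `component`, `n_nodes`).
#' @export
build_reaction_network <- function(reactions) {
  if (anyDuplicated(reactions$reaction_id)) {
    abort("`reactions` must be deduplicated by reaction_id")
  }
  empty <- vapply(seq_len(nrow(reactions)), function(i) {
    length(reactions$substrates[[i]]) == 0 ||
      length(reactions$products[[i]]) == 0
  }, logical(1))
  if (any(empty)) {
    abort(c("reaction(s) with an empty side:",
            paste(head(reactions$reaction_id[empty], 10), collapse = ", ")))
  }
  edge_list <- lapply(seq_len(nrow(reactions)), function(i) {
    id <- reactions$reaction_id[i]
    subs <- names(reactions$substrates[[i]])
    prods <- names(reactions$products[[i]])
    fwd <- rbind(cbind(subs, id), cbind(id, prods))
    if (isTRUE(reactions$reversible[i])) {
      rbind(fwd, cbind(prods, id), cbind(id, subs))
    } else {
      fwd
    }
  })
  edges <- do.call(rbind, edge_list)
  mets <- sort(unique(unlist(lapply(seq_len(nrow(reactions)), function(i) {
    c(names(reactions$substrates[[i]]), names(reactions$products[[i]]))
  }))))
  overlap <- intersect(mets, reactions$reaction_id)
  if (length(overlap) > 0) {
    abort(c("compound and reaction identifiers must be disjoint:",
            paste(head(overlap, 10), collapse = ", ")))
  }
  vertices <- data.frame(
    name = c(mets, reactions$reaction_id),
    kind = c(rep("metabolite", length(mets)),
             rep("reaction", nrow(reactions))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = vertices
  )
  skeleton <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  deg <- igraph::degree(skeleton)
  comp <- igraph::components(skeleton)
  # renumber components by decreasing size (ties by smallest member name)
  sizes <- comp$csize
  first_name <- vapply(seq_along(sizes), function(k) {
    min(igraph::V(skeleton)$name[comp$membership == k])
  }, character(1))
  ord <- order(-sizes, first_name)
  relabel <- match(seq_along(sizes), ord)
  nodes <- tibble(
    name = igraph::V(g)$name,
    kind = igraph::V(g)$kind,
    degree = as.integer(deg[igraph::V(g)$name]),
    component = relabel[comp$membership[igraph::V(g)$name]]
  )
  list(
    graph = g,
    nodes = nodes,
    components = nodes |>
      dplyr::count(.data$component, name = "n_nodes") |>
      dplyr::arrange(.data$component)
  )
}

#' Score reactions by taxonomic distribution of their encoding families
#'
#' For each reaction, counts the taxonomic groups in which at least one of
#' its encoding families is present in at least one genome. Reactions with a
#' narrow distribution score low; those encoded in many groups score high.
#'
#' @param reactions A reaction tibble with an `encoding_families` list-column
#'   (see [families_to_reactions()]).
#' @param presence A presence tibble (see [filter_families()]).
#' @return The reaction tibble with an added integer `group_count` column.
#' @export
score_reactions <- function(reactions, presence) {
  check_columns(presence, c("family_id", "group", "genomes_with_family"),
                "presence")
  present <- presence |>
    dplyr::filter(.data$genomes_with_family >= 1)
  groups_by_family <- split(present$group, present$family_id)
  reactions$group_count <- vapply(reactions$encoding_families, function(fams) {
    length(unique(unlist(groups_by_family[fams], use.names = FALSE)))
  }, integer(1))
  reactions
}
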