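# Network expansion (scope) and the score-ordered greedy reduction that
# finds a 1-minimal set of candidate reactions completing target production.

# internal: reactions -> list of firing rules (need = substrates, add = products)
reaction_rules <- function(reactions) {
  rules <- list()
  for (i in seq_len(nrow(reactions))) {
    subs <- names(reactions$substrates[[i]])
    prods <- names(reactions$products[[i]])
    rules[[length(rules) + 1]] <- list(need = subs, add = prods)
    if (isTRUE(reactions$reversible[i])) {
      rules[[length(rules) + 1]] <- list(need = prods, add = subs)
    }
  }
  rules
}

#' Compute the metabolic scope of a seed set (network expansion)
#'
#' The scope is the least fixed point of repeatedly firing reactions whose
#' substrates are all already producible, starting from the seed compounds;
#' reversible reactions may fire in either direction. The result does not
#' depend on the order in which reactions are considered.
#'
#' @param reactions A parsed reaction tibble.
#' @param seeds Character vector of seed compound ids. Seeds not occurring in
#'   any reaction are allowed (and reported via a message).
#' @return Sorted character vector of producible compounds (always a
#'   superset of the seeds).
#' @export
#' @examples
#' rx <- parse_reactions(tibble::tibble(
#'   reaction_id = c("R1", "R2"),
#'   equation = c("A => B", "B <=> C")
#' ))$reactions
#' compute_scope(rx, "A")
compute_scope <- function(reactions, seeds) {
  seeds <- unique(as.character(seeds))
  known <- unique(unlist(lapply(seq_len(nrow(reactions)),
    function(i) c(names(reactions$substrates[[i]]),
                  names(reactions$products[[i]])))))
  universe <- unique(c(seeds, known))
  unknown <- setdiff(seeds, known)
  if (length(unknown) > 0 && nrow(reactions) > 0) {
    inform(sprintf("%d seed(s) do not occur in any reaction", length(unknown)))
  }
  in_scope <- setNames(logical(length(universe)), universe)
  in_scope[seeds] <- TRUE
  rules <- reaction_rules(reactions)
  fired <- logical(length(rules))
  repeat {
    changed <- FALSE
    for (r in seq_along(rules)) {
      if (fired[r]) next
      if (all(in_scope[rules[[r]]$need])) {
        fired[r] <- TRUE
        add <- rules[[r]]$add
        if (!all(in_scope[add])) {
          in_scope[add] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sort(names(in_scope)[in_scope])
}

# internal: coerce a targets argument to a tibble(compound_id, category)
as_target_table <- function(targets) {
  if (is.data.frame(targets)) {
    check_columns(targets, "compound_id", "targets")
    if (!"category" %in% names(targets)) targets$category <- NA_character_
    as_tibble(targets)[, c("compound_id", "category")]
  } else {
    tibble(compound_id = as.character(targets), category = NA_character_)
  }
}

#' Assess which target metabolites a network can produce
#'
#' Two producibility notions are supported. `"produced_by_any"` (the
#' default): a target is producible when some reaction in the network has it
#' as a product (either side for reversible reactions).
#' `"scope_from_seeds"`: a target is producible when it lies in
#' [compute_scope()] of the given seeds.
#'
#' @param reactions A parsed reaction tibble.
#' @param targets Target compounds: a character vector or a data frame with
#'   columns `compound_id` and optionally `category`.
#' @param mode `"produced_by_any"` or `"scope_from_seeds"`.
#' @param seeds Seed compounds, required for `"scope_from_seeds"`.
#' @return A tibble with columns `compound_id`, `category`, `producible`,
#'   sorted by `compound_id`.
#' @export
producible_targets <- function(reactions, targets,
                               mode = c("produced_by_any",
                                        "scope_from_seeds"),
                               seeds = NULL) {
  mode <- match.arg(mode)
  tt <- as_target_table(targets)
  producible_set <- if (mode == "produced_by_any") {
    unique(unlist(lapply(seq_len(nrow(reactions)), function(i) {
      p <- names(reactions$products[[i]])
      if (isTRUE(reactions$reversible[i])) {
        c(p, names(reactions$substrates[[i]]))
      } else {
        p
      }
    })))
  } else {
    if (is.null(seeds)) abort("`seeds` is required for mode scope_from_seeds")
    compute_scope(reactions, seeds)
  }
  tt |>
    dplyr::mutate(producible = .data$compound_id %in% producible_set) |>
    dplyr::arrange(.data$compound_id)
}

#' Default seed set: compounds appearing only as substrates
#'
#' A convenience default for scope-mode analyses: the network's external
#' inputs, i.e. compounds that occur as a substrate of some reaction but are
#' never produced (never a product of an irreversible reaction nor on either
#' side of a reversible one).
#'
#' @param reactions A parsed reaction tibble.
#' @return Sorted character vector of compound ids.
#' @export
default_seeds <- function(reactions) {
  subs <- unique(unlist(lapply(seq_len(nrow(reactions)), function(i) {
    s <- names(reactions$substrates[[i]])
    if (isTRUE(reactions$reversible[i])) character(0) else s
  })))
  produced <- unique(unlist(lapply(seq_len(nrow(reactions)), function(i) {
    p <- names(reactions$products[[i]])
    if (isTRUE(reactions$reversible[i])) {
      c(p, names(reactions$substrates[[i]]))
    } else {
      p
    }
  })))
  sort(setdiff(subs, produced))
}

#' Greedy score-ordered reduction to a minimal completing reaction set
#'
#' Starting from the full network (protected core plus removable
#' candidates), candidate reactions are visited in order of increasing score
#' (ties broken by lexicographic reaction id) and each is removed temporarily;
#' if all target metabolites remain producible the removal is made permanent.
#' Full passes repeat until a pass removes nothing. Core reactions are never
#' removal candidates. The retained candidate set is 1-minimal: removing any
#' single retained candidate breaks the production of at least one target
#' (this is verified and recorded on the result).
#'
#' @param core Parsed reaction tibble of protected reactions.
#' @param candidates Parsed reaction tibble of removable reactions; must be
#'   disjoint from `core` by `reaction_id`.
#' @param targets Targets as in [producible_targets()].
#' @param scores Reaction scores: a data frame with `reaction_id`, `score`, or
#'   a named numeric vector. Candidates missing a score get 0.
#' @param mode,seeds Producibility notion, as in [producible_targets()].
#' @param strict_core Additionally require that a removal does not increase
#'   the number of connected components (of the undirected bipartite
#'   skeleton) containing core reactions. Default `FALSE`.
#' @return An object of class `reduction_result`: a list with `retained` and
#'   `removed` candidate tibbles (the latter with the removal `step` and
#'   `pass`), `producible_before` / `producible_after` target tibbles
#'   (core alone vs. core plus retained candidates), `completing_families`
#'   (union of the retained candidates' encoding families, if present),
#'   `n_passes`, `minimal` (logical, the 1-minimality check) and `mode`.
#'   [tidy()] and [glance()] methods are available.
#' @export
reduce_network <- function(core, candidates, targets, scores = NULL,
                           mode = c("produced_by_any", "scope_from_seeds"),
                           seeds = NULL, strict_core = FALSE) {
  mode <- match.arg(mode)
  if (length(intersect(core$reaction_id, candidates$reaction_id)) > 0) {
    abort("`core` and `candidates` must be disjoint by reaction_id")
  }
  tt <- as_target_table(targets)
  score_map <- if (is.null(scores)) {
    numeric(0)
  } else if (is.data.frame(scores)) {
    check_columns(scores, c("reaction_id", "score"), "scores")
    setNames(scores$score, scores$reaction_id)
  } else {
    scores
  }
  cand_scores <- unname(score_map[candidates$reaction_id])
  cand_scores[is.na(cand_scores)] <- 0
  ord <- order(cand_scores, candidates$reaction_id)
  candidates <- candidates[ord, , drop = FALSE]
  cand_scores <- cand_scores[ord]

  check_targets <- function(rxns) {
    pt <- producible_targets(rxns, tt, mode = mode, seeds = seeds)
    all(pt$producible)
  }
  core_components <- function(rxns) {
    net <- build_reaction_network(rxns)
    sum(vapply(split(net$nodes$kind, net$nodes$component),
               function(k) any(k == "reaction"), logical(1)) &
          vapply(split(net$nodes$name, net$nodes$component),
                 function(nm) any(nm %in% core$reaction_id), logical(1)))
  }
  full <- dplyr::bind_rows(core, candidates)
  if (!check_targets(full)) {
    pt <- producible_targets(full, tt, mode = mode, seeds = seeds)
    abort(c("targets unproducible even with all candidate reactions:",
            paste(pt$compound_id[!pt$producible], collapse = ", ")))
  }
  base_core_comp <- if (strict_core) core_components(full) else NA_integer_

  retained <- rep(TRUE, nrow(candidates))
  removed_step <- rep(NA_integer_, nrow(candidates))
  removed_pass <- rep(NA_integer_, nrow(candidates))
  step <- 0L
  pass <- 0L
  repeat {
    pass <- pass + 1L
    removed_this_pass <- 0L
    for (i in seq_len(nrow(candidates))) {
      if (!retained[i]) next
      trial <- retained
      trial[i] <- FALSE
      rxns <- dplyr::bind_rows(core, candidates[trial, , drop = FALSE])
      ok <- check_targets(rxns)
      if (ok && strict_core) {
        ok <- core_components(rxns) <= base_core_comp
      }
      if (ok) {
        retained <- trial
        step <- step + 1L
        removed_step[i] <- step
        removed_pass[i] <- pass
        removed_this_pass <- removed_this_pass + 1L
      }
    }
    if (removed_this_pass == 0L) break
  }

  # post-hoc 1-minimality check on the retained candidate set
  minimal <- TRUE
  for (i in which(retained)) {
    trial <- retained
    trial[i] <- FALSE
    if (check_targets(dplyr::bind_rows(core,
                                       candidates[trial, , drop = FALSE]))) {
      minimal <- FALSE
      break
    }
  }

  retained_tbl <- candidates[retained, , drop = FALSE] |>
    dplyr::mutate(score = cand_scores[retained])
  removed_tbl <- candidates[!retained, , drop = FALSE] |>
    dplyr::mutate(score = cand_scores[!retained],
                  step = removed_step[!retained],
                  pass = removed_pass[!retained]) |>
    dplyr::arrange(.data$step)
  completing <- if ("encoding_families" %in% names(retained_tbl)) {
    sort(unique(unlist(retained_tbl$encoding_families)))
  } else {
    character(0)
  }
  structure(
    list(
      retained = retained_tbl,
      removed = removed_tbl,
      producible_before = producible_targets(core, tt, mode = mode,
                                             seeds = seeds),
      producible_after = producible_targets(
        dplyr::bind_rows(core, dplyr::select(retained_tbl, -"score")), tt,
        mode = mode, seeds = seeds),
      completing_families = completing,
      n_passes = pass,
      minimal = minimal,
      mode = mode
    ),
    class = "reduction_result"
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("Network reduction (mode:", x$mode, ")\n")
  cat(sprintf("  candidates: %d retained, %d removed (%d pass(es))\n",
              nrow(x$retained), nrow(x$removed), x$n_passes))
  cat(sprintf("  targets producible: %d/%d before, %d/%d after\n",
              sum(x$producible_before$producible),
              nrow(x$producible_before),
              sum(x$producible_after$producible),
              nrow(x$producible_after)))
  cat(sprintf("  retained set 1-minimal: %s\n", x$minimal))
  invisible(x)
}
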