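# Ancestral root-state estimation under the F81 substitution model, with
# across-tree aggregation, and verticality annotation of reactions.

#' F81 root-state posterior for a discrete trait
#'
#' Computes the marginal posterior distribution of the trait state at the
#' root of a rooted tree under the F81 model: substitution towards the
#' equilibrium frequencies `pi` at a uniform rate, with transition
#' probability `P(i -> j, t) = pi_j + (delta_ij - pi_j) exp(-beta t)` and
#' `beta = 1 / (1 - sum(pi^2))`. Conditional likelihoods are propagated by a
#' post-order pruning recursion; the root posterior is the normalized
#' product of `pi` and the root conditional likelihood. Tips with unknown
#' state contribute a vector of ones.
#'
#' The prediction is the posterior argmax (all states on an exact tie); in
#' addition, states whose posterior is within a factor 2 of the maximum are
#' co-reported, mirroring the spirit of marginal-posterior prediction rules
#' that return state sets rather than single states.
#'
#' @param tree A rooted ape `phylo` with branch lengths.
#' @param tip_states Named character vector (names = leaf labels) of
#'   observed states; `NA` marks unknown tips. A state outside the declared
#'   state set is an error.
#' @param states Optional character vector declaring the state space;
#'   defaults to the states observed at the tips.
#' @param freqs Equilibrium frequencies: `"empirical"` (pooled over known
#'   tips; the default), `"uniform"`, or a named numeric vector over
#'   `states`.
#' @return A tibble with columns `state`, `posterior`, `predicted` (argmax,
#'   ties included) and `co_reported` (within factor 2 of the maximum),
#'   sorted by decreasing posterior. The posterior sums to 1.
#' @export
f81_root_posterior <- function(tree, tip_states, states = NULL,
                               freqs = "empirical") {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (!ape::is.rooted(tree)) abort("`tree` must be rooted")
  tips <- tree$tip.label
  obs <- tip_states[tips]
  names(obs) <- tips
  if (all(is.na(obs))) abort("at least one tip state must be known")
  states <- states %||% sort(unique(obs[!is.na(obs)]))
  bad <- setdiff(unique(obs[!is.na(obs)]), states)
  if (length(bad) > 0) {
    abort(c("tip state(s) outside the declared state set:",
            paste(bad, collapse = ", ")))
  }
  k <- length(states)
  pi <- if (identical(freqs, "empirical")) {
    tab <- table(factor(obs[!is.na(obs)], levels = states))
    as.numeric(tab) / sum(tab)
  } else if (identical(freqs, "uniform")) {
    rep(1 / k, k)
  } else {
    if (is.null(names(freqs)) || !setequal(names(freqs), states)) {
      abort("numeric `freqs` must be named over the state set")
    }
    as.numeric(freqs[states] / sum(freqs))
  }
  names(pi) <- states
  sum_pi2 <- sum(pi^2)
  if (sum_pi2 >= 1 - 1e-12) {
    # degenerate frequencies (all mass on one state): posterior equals pi
    post <- pi
  } else {
    beta <- 1 / (1 - sum_pi2)
    ntip <- length(tips)
    nn <- ntip + tree$Nnode
    L <- matrix(1, nn, k)
    for (i in seq_len(ntip)) {
      if (!is.na(obs[i])) {
        L[i, ] <- as.numeric(states == obs[i])
      }
    }
    eo <- ape::reorder.phylo(tree, "postorder")
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]
      ch <- eo$edge[e, 2]
      t <- eo$edge.length[e]
      ebt <- exp(-beta * t)
      # P[i, j] = pi_j + (delta - pi_j) e^{-beta t}
      P <- matrix(pi * (1 - ebt), k, k, byrow = TRUE) + diag(ebt, k)
      L[par, ] <- L[par, ] * as.numeric(P %*% L[ch, ])
    }
    root <- ntip + 1L
    post <- pi * L[root, ]
    if (sum(post) <= 0) abort("zero likelihood at the root")
    post <- post / sum(post)
  }
  mx <- max(post)
  tibble(
    state = states,
    posterior = unname(post),
    predicted = post == mx,
    co_reported = post >= mx / 2
  ) |>
    dplyr::arrange(dplyr::desc(.data$posterior), .data$state)
}

#' Aggregate root-state predictions across trees
#'
#' Tallies how often each state is predicted at the root across a collection
#' of trees; the modal state(s) — those with the highest frequency — are the
#' best overall root-state estimate. Ties are reported as ties.
#'
#' @param predictions A data frame with columns `tree_id`, `state` (one row
#'   per predicted state per tree; trees with tied predictions contribute
#'   one row per tied state).
#' @return A tibble with columns `state`, `n_trees`, `frequency` (fraction
#'   of trees predicting the state) and `modal`.
#' @export
aggregate_root_states <- function(predictions) {
  check_columns(predictions, c("tree_id", "state"), "predictions")
  if (nrow(predictions) == 0) abort("no predictions supplied")
  n_total <- dplyr::n_distinct(predictions$tree_id)
  out <- predictions |>
    dplyr::distinct(.data$tree_id, .data$state) |>
    dplyr::count(.data$state, name = "n_trees") |>
    dplyr::mutate(frequency = .data$n_trees / n_total,
                  modal = .data$n_trees == max(.data$n_trees)) |>
    dplyr::arrange(dplyr::desc(.data$n_trees), .data$state)
  out
}

#' Annotate reactions with the mean verticality of their encoding families
#'
#' Verticality scores a gene family's tendency to be inherited vertically
#' rather than laterally (here on a 0-24 scale, higher = more vertical).
#' Each reaction receives the unweighted mean over its encoding families
#' that have a verticality entry; families without entries are skipped (and
#' counted), and reactions with no scored family get `NA` and are flagged.
#'
#' @param reactions A reaction tibble with an `encoding_families`
#'   list-column.
#' @param family_verticality A data frame with columns `family_id`,
#'   `verticality`.
#' @return The reaction tibble with added columns `mean_verticality`,
#'   `n_families_scored` and `verticality_missing` (no scored family).
#' @export
annotate_verticality <- function(reactions, family_verticality) {
  check_columns(family_verticality, c("family_id", "verticality"),
                "family_verticality")
  vmap <- setNames(family_verticality$verticality,
                   family_verticality$family_id)
  vals <- lapply(reactions$encoding_families, function(fams) {
    v <- vmap[fams]
    v[!is.na(v)]
  })
  reactions$mean_verticality <- vapply(vals, function(v) {
    if (length(v) > 0) mean(v) else NA_real_
  }, numeric(1))
  reactions$n_families_scored <- lengths(vals)
  reactions$verticality_missing <- reactions$n_families_scored == 0L
  n_missing <- sum(reactions$verticality_missing)
  if (n_missing > 0) {
    inform(sprintf("%d reaction(s) have no verticality-scored family",
                   n_missing))
  }
  reactions
}
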