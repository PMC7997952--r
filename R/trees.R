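# MAD rooting and rooted-tree analyses (root-to-tip divergence, sister
# diversity). Trees are ape "phylo" objects; input gene trees are treated as
# unrooted and must carry branch lengths.

# internal: logical matrix, row = node, col = tip; TRUE when the tip lies in
# the subtree below the node (in the stored edge orientation)
tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  below <- matrix(FALSE, nn, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    below[eo[k, 1], ] <- below[eo[k, 1], ] | below[eo[k, 2], ]
  }
  below
}

#' Root a gene tree by minimal ancestor deviation (MAD)
#'
#' Evaluates every branch of the unrooted tree as a candidate root. For a
#' root placed at a given position on a branch, every leaf pair `(i, j)` has
#' an induced ancestor (the pair's meeting point on the path towards the
#' root); under a strict molecular clock that ancestor would be equidistant
#' from both leaves, so the relative deviation
#' `|2 d(ancestor, i) / d(i, j) - 1|` measures the departure from clocklike
#' behaviour. The MAD score of a candidate root is the root-mean-square of
#' these deviations over all leaf pairs; the optimal position on each branch
#' has a closed-form minimizer (clamped to the branch). Branches are
#' returned sorted by their MAD score. The root is flagged ambiguous when a
#' second branch matches the minimum within relative tolerance `tie_tol`;
#' the ambiguity index is the ratio of the best to the second-best score.
#'
#' Leaf pairs at zero path distance are skipped (denominator guard).
#'
#' @param tree An ape `phylo` with branch lengths and at least 3 leaves. Any
#'   rooting of the input representation is ignored.
#' @param tie_tol Relative tolerance for root ties. Default 1e-6.
#' @return An object of class `mad_root`: a list with the unrooted working
#'   `tree`, a `table` tibble (one row per branch, best first: `edge`,
#'   `parent`, `child`, `length`, `position` — root position as the fraction
#'   of the branch measured from the child end — and `mad`), and fields
#'   `best_edge`, `best_position`, `mad_value`, `ambiguity_index`,
#'   `is_ambiguous`. Use [root_tree()] to materialize the rooted tree and
#'   [tidy()]/[glance()] for tabular summaries.
#' @export
mad_root <- function(tree, tie_tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (is.null(tree$edge.length)) abort("`tree` must have branch lengths")
  ntip <- length(tree$tip.label)
  if (ntip < 3) abort("MAD rooting requires at least 3 leaves")
  u <- ape::unroot(tree)
  el <- u$edge.length
  if (any(!is.finite(el)) || any(el < 0)) {
    abort("branch lengths must be finite and non-negative")
  }
  if (all(el == 0)) abort("degenerate tree: all branch lengths are zero")
  D <- ape::dist.nodes(u)
  tips <- seq_len(ntip)
  Dt <- D[tips, tips, drop = FALSE]
  below <- tips_below(u)
  nedge <- nrow(u$edge)
  mad <- numeric(nedge)
  pos <- numeric(nedge)

  side_ss <- function(idx, danchor) {
    # squared deviations for same-side pairs: |d(a,i) - d(a,j)| / d(i,j)
    if (length(idx) < 2) return(c(0, 0))
    d <- Dt[idx, idx, drop = FALSE]
    dev <- abs(outer(danchor, danchor, "-")) / d
    use <- upper.tri(d) & d > 0
    c(sum(dev[use]^2), sum(use))
  }

  for (e in seq_len(nedge)) {
    p <- u$edge[e, 1]
    ch <- u$edge[e, 2]
    l <- el[e]
    A <- which(below[ch, ])     # child-side tips
    B <- which(!below[ch, ])    # parent-side tips
    dAB <- Dt[A, B, drop = FALSE]
    dcA <- D[ch, A]
    dpB <- D[p, B]
    use <- dAB > 0
    # spanning pairs: deviation(x) = 2 (d(child,i) + x) / d(i,j) - 1
    a <- 2 / dAB
    t0 <- 2 * dcA / dAB - 1     # dcA recycles down columns (rows = A)
    sa2 <- sum(a[use]^2)
    sat <- sum((a * t0)[use])
    x <- if (sa2 > 0) min(max(-sat / sa2, 0), l) else 0
    ss_span <- sum(((t0 + a * x)[use])^2)
    sA <- side_ss(A, dcA)
    sB <- side_ss(B, dpB)
    npairs <- sum(use) + sA[2] + sB[2]
    mad[e] <- if (npairs > 0) {
      sqrt((ss_span + sA[1] + sB[1]) / npairs)
    } else {
      NA_real_
    }
    pos[e] <- if (l > 0) x / l else 0
  }

  ord <- order(mad)
  table <- tibble(
    edge = ord,
    parent = u$edge[ord, 1],
    child = u$edge[ord, 2],
    length = el[ord],
    position = pos[ord],
    mad = mad[ord]
  )
  best <- table$mad[1]
  second <- if (nrow(table) >= 2) table$mad[2] else NA_real_
  ai <- if (is.na(second)) {
    NA_real_
  } else if (second > 0) {
    best / second
  } else {
    1
  }
  ambiguous <- if (is.na(second)) {
    FALSE
  } else if (best == 0) {
    second == 0
  } else {
    second <= best * (1 + tie_tol)
  }
  structure(
    list(
      tree = u,
      table = table,
      best_edge = table$edge[1],
      best_position = table$position[1],
      mad_value = best,
      ambiguity_index = ai,
      is_ambiguous = ambiguous,
      tie_tol = tie_tol
    ),
    class = "mad_root"
  )
}

#' @export
print.mad_root <- function(x, ...) {
  cat(sprintf(
    "MAD root: edge %d (position %.4f from child), mad = %.6g\n",
    x$best_edge, x$best_position, x$mad_value))
  cat(sprintf("ambiguity index = %.6g; ambiguous: %s\n",
              x$ambiguity_index, x$is_ambiguous))
  invisible(x)
}

#' Keep only trees with an unambiguous MAD root
#'
#' @param inferences A list of [mad_root()] objects.
#' @return The sublist with `is_ambiguous == FALSE`; the number removed is
#'   attached as attribute `n_ambiguous` and reported via a message.
#' @export
filter_ambiguous <- function(inferences) {
  amb <- vapply(inferences, function(x) isTRUE(x$is_ambiguous), logical(1))
  inform(sprintf("%d of %d trees have ambiguous roots; %d retained",
                 sum(amb), length(inferences), sum(!amb)))
  out <- inferences[!amb]
  attr(out, "n_ambiguous") <- sum(amb)
  out
}

# internal: insert a root node on edge `edge_idx` at distance `x` from the
# child end and reorient the tree; returns a rooted phylo whose root node is
# ntip + 1 (binary root with two children)
reroot_at <- function(tree, edge_idx, x) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  p <- tree$edge[edge_idx, 1]
  ch <- tree$edge[edge_idx, 2]
  l <- tree$edge.length[edge_idx]
  if (x < 0 || x > l) abort("root position outside the branch")
  R <- nn + 1L
  from <- c(tree$edge[-edge_idx, 1], R, R)
  to <- c(tree$edge[-edge_idx, 2], ch, p)
  w <- c(tree$edge.length[-edge_idx], x, l - x)
  # undirected adjacency
  adj <- vector("list", nn + 1L)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- rbind(adj[[from[k]]], c(to[k], w[k]))
    adj[[to[k]]] <- rbind(adj[[to[k]]], c(from[k], w[k]))
  }
  # iterative preorder from R, assigning new internal ids in visit order
  new_id <- integer(nn + 1L)
  next_internal <- ntip + 1L
  stack <- list(c(R, 0L, NA_real_))  # node, parent(old id), edge length
  edges_from <- integer(0)
  edges_to <- integer(0)
  edges_len <- numeric(0)
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]
    par <- top[2]
    len <- top[3]
    if (node <= ntip) {
      new_id[node] <- node
    } else {
      new_id[node] <- next_internal
      next_internal <- next_internal + 1L
    }
    if (par != 0L) {
      edges_from <- c(edges_from, new_id[par])
      edges_to <- c(edges_to, new_id[node])
      edges_len <- c(edges_len, len)
    }
    nbrs <- adj[[node]]
    if (!is.null(nbrs)) {
      for (k in rev(seq_len(nrow(nbrs)))) {
        if (nbrs[k, 1] != par) {
          stack[[length(stack) + 1]] <- c(nbrs[k, 1], node, nbrs[k, 2])
        }
      }
    }
  }
  out <- list(
    edge = cbind(as.integer(edges_from), as.integer(edges_to),
                 deparse.level = 0),
    edge.length = edges_len,
    tip.label = tree$tip.label,
    Nnode = tree$Nnode + 1L
  )
  class(out) <- "phylo"
  attr(out, "order") <- "cladewise"
  out
}

#' Materialize the rooted tree implied by a MAD inference
#'
#' Inserts the root node on the inferred branch at the inferred position and
#' reorients the tree.
#'
#' @param inference A [mad_root()] object.
#' @param rank Which candidate branch to use (1 = best). Default 1.
#' @return A rooted ape `phylo` whose root has two children.
#' @export
root_tree <- function(inference, rank = 1) {
  if (!inherits(inference, "mad_root")) {
    abort("`inference` must come from mad_root()")
  }
  row <- inference$table[rank, ]
  reroot_at(inference$tree, row$edge, row$position * row$length)
}

#' Normalized root-to-tip distances
#'
#' Computes, for every leaf of a rooted tree, the root-to-tip distance as
#' either the sum of branch lengths along the path (`"branch_length"`, the
#' phenetic distance) or the number of branching events along the path
#' (`"node_depth"`; the root's initial split counts, so a direct child of
#' the root has depth 1). Distances are normalized by the per-tree maximum
#' so values lie in `[0, 1]` with at least one leaf exactly at 1.
#'
#' @param tree A rooted ape `phylo` (e.g. from [root_tree()]).
#' @param metric `"branch_length"` or `"node_depth"`.
#' @return A tibble with columns `leaf`, `distance`, `normalized_distance`.
#' @export
root_to_tip <- function(tree, metric = c("branch_length", "node_depth")) {
  metric <- match.arg(metric)
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (!ape::is.rooted(tree)) abort("`tree` must be rooted")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- rep(NA_real_, nn)
  root <- ntip + 1L
  depth[root] <- 0
  eo <- ape::reorder.phylo(tree, "cladewise")
  step <- if (metric == "branch_length") eo$edge.length else
    rep(1, nrow(eo$edge))
  for (k in seq_len(nrow(eo$edge))) {
    depth[eo$edge[k, 2]] <- depth[eo$edge[k, 1]] + step[k]
  }
  d <- depth[seq_len(ntip)]
  m <- max(d)
  if (m <= 0) abort("all root-to-tip distances are zero; cannot normalize")
  tibble(leaf = tree$tip.label, distance = d, normalized_distance = d / m)
}

#' Per-tree, per-group minimum divergence and across-tree means
#'
#' Scores each taxonomic group in each tree by its least-diverged affiliated
#' genome: the minimum normalized root-to-tip distance over the group's
#' leaves (ties broken by leaf label). Groups absent from a tree contribute
#' no record for that tree.
#'
#' @param distances A data frame of per-leaf distances with columns
#'   `tree_id`, `leaf`, `normalized_distance` (stack [root_to_tip()] results
#'   over trees, adding `tree_id`; a `metric` column, if present, is kept as
#'   a grouping variable).
#' @param groups Leaf-to-group mapping: a data frame with `genome_id`,
#'   `group` or a named character vector. Leaf labels are genome ids.
#' @return A tibble with one row per tree (x metric) x group: `tree_id`,
#'   (`metric`,) `group`, `normalized_distance` (the minimum) and
#'   `representative` (the leaf attaining it).
#' @export
group_divergence <- function(distances, groups) {
  check_columns(distances, c("tree_id", "leaf", "normalized_distance"),
                "distances")
  gm <- as_group_map(groups)
  unknown <- setdiff(unique(distances$leaf), names(gm))
  if (length(unknown) > 0) {
    abort(c("leaves without a group mapping:",
            paste(head(unknown, 10), collapse = ", ")))
  }
  keys <- c("tree_id", intersect("metric", names(distances)), "group")
  as_tibble(distances) |>
    dplyr::mutate(group = unname(gm[.data$leaf])) |>
    dplyr::arrange(.data$normalized_distance, .data$leaf) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE) |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(keys)),
      normalized_distance = .data$normalized_distance,
      representative = .data$leaf
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Across-tree mean divergence per group
#'
#' @param records Output of [group_divergence()].
#' @return A tibble with the mean normalized distance and the number of
#'   trees in which each group occurs, per metric if a `metric` column is
#'   present.
#' @export
divergence_means <- function(records) {
  keys <- c(intersect("metric", names(records)), "group")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_distance = mean(.data$normalized_distance),
                     n_trees = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Sister-clade diversity of each taxonomic group in a rooted tree
#'
#' For every group present in the tree, identifies its maximal pure clades
#' (subtrees whose leaves all belong to the group and whose parent subtree
#' does not) and, for each, counts the distinct other groups present in the
#' clade's sister (the leaves under the parent's other children; for a child
#' of the root this is the rest of the tree). The group's score is the
#' maximum count over its pure clades. Scores lie in `[1, G - 1]` for `G`
#' groups in the tree: a maximal pure clade's sister always contains at
#' least one other group.
#'
#' A tree whose leaves all belong to one group yields no records.
#'
#' @param tree A rooted ape `phylo`.
#' @param groups Leaf-to-group mapping as in [group_divergence()].
#' @return A tibble with columns `group`, `score`, `pure_clade_count`.
#' @export
sister_diversity <- function(tree, groups) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (!ape::is.rooted(tree)) abort("`tree` must be rooted")
  gm <- as_group_map(groups)
  unknown <- setdiff(tree$tip.label, names(gm))
  if (length(unknown) > 0) {
    abort(c("leaves without a group mapping:",
            paste(head(unknown, 10), collapse = ", ")))
  }
  leaf_groups <- unname(gm[tree$tip.label])
  levs <- sort(unique(leaf_groups))
  G <- length(levs)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (G < 2) {
    return(tibble(group = character(), score = integer(),
                  pure_clade_count = integer()))
  }
  # groups present below each node
  below <- matrix(FALSE, nn, G)
  below[cbind(seq_len(ntip), match(leaf_groups, levs))] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  parent <- integer(nn)
  for (k in seq_len(nrow(eo))) {
    below[eo[k, 1], ] <- below[eo[k, 1], ] | below[eo[k, 2], ]
    parent[eo[k, 2]] <- eo[k, 1]
  }
  root <- ntip + 1L
  pure <- rowSums(below) == 1L
  rec_group <- integer(0)
  rec_score <- integer(0)
  for (v in which(pure)) {
    if (v == root) next                       # single-group tree
    if (pure[parent[v]]) next                 # not maximal
    g_idx <- which(below[v, ])
    sibs <- eo[eo[, 1] == parent[v] & eo[, 2] != v, 2]
    sister_groups <- colSums(below[sibs, , drop = FALSE]) > 0
    rec_group <- c(rec_group, g_idx)
    rec_score <- c(rec_score, sum(sister_groups[-g_idx]))
  }
  if (length(rec_group) == 0) {
    return(tibble(group = character(), score = integer(),
                  pure_clade_count = integer()))
  }
  gs <- sort(unique(rec_group))
  tibble(
    group = levs[gs],
    score = as.integer(vapply(gs, function(g) max(rec_score[rec_group == g]),
                              numeric(1))),
    pure_clade_count = as.integer(tabulate(rec_group, G)[gs])
  )
}
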