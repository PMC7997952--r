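# Seeded synthetic-data generators. Every generator is a pure function of
# its parameters and seed, and produces inputs in the same shapes the
# analysis functions consume, together with the planted ground truth.

scale_to_depth <- function(t, depth) {
  t$edge.length <- t$edge.length * depth /
    max(ape::node.depth.edgelength(t))
  t
}

# newick fragment for an ultrametric subtree over `labels` with total depth
# `depth`; `extra` is depth to add onto the attachment branch (single-tip
# subtrees have no internal structure to carry it)
subtree_nwk <- function(labels, depth) {
  if (length(labels) == 1) {
    return(list(str = labels, extra = depth))
  }
  t <- scale_to_depth(ape::rcoal(length(labels), tip.label = labels), depth)
  list(str = sub(";$", "", ape::write.tree(t)), extra = 0)
}

# replace the tip `tip_label:len` in a newick string by a subtree fragment
graft_nwk <- function(nwk, tip_label, sub) {
  pattern <- paste0("(?<![A-Za-z0-9_])", tip_label, ":([0-9.eE+-]+)")
  m <- regexpr(pattern, nwk, perl = TRUE)
  if (m < 0) abort(sprintf("tip %s not found in newick string", tip_label))
  len <- as.numeric(base::sub("^.*:", "", regmatches(nwk, m)))
  regmatches(nwk, m) <- paste0(sub$str, ":",
                               format(len + sub$extra, digits = 15))
  nwk
}

#' Define a synthetic world: species history plus planted parameters
#'
#' Builds the ground truth from which all synthetic gene-tree inputs derive:
#' `n_groups` taxonomic groups of `genomes_per_group` genomes each, related
#' by an ultrametric species history (unit depth) in which every group is
#' monophyletic. The designated basal group attaches directly at the root —
#' it is the planted earliest-diverging lineage — while the remaining groups
#' sit on a random coalescent backbone. Gene trees are later derived from
#' this history by gene loss, lateral transfers and branch-rate noise
#' ([simulate_gene_trees()]).
#'
#' @param seed Integer seed; the world and everything derived from it are
#'   deterministic functions of it.
#' @param n_groups Number of taxonomic groups (>= 2). Default 8.
#' @param genomes_per_group Genomes per group. Default 3.
#' @param basal_group Label of the planted earliest-diverging group;
#'   defaults to the first group.
#' @param lgt_rate Expected lateral transfers per gene-tree branch.
#'   Default 0.05.
#' @param loss_prob Per-genome gene-loss probability per gene tree.
#'   Default 0.1.
#' @param rate_noise_sd Log-sd of the multiplicative lognormal branch-length
#'   noise. Default 0.3.
#' @param trait_states Discrete trait state space (first state is the
#'   planted root state). Default `c("rod", "coccus")`.
#' @return An object of class `synthetic_world`: a list with `seed`,
#'   `groups` (tibble `genome_id`, `group`), `basal_group`, `species_tree`
#'   (rooted ultrametric `phylo`), the rate parameters, `trait_states` and
#'   `root_state`.
#' @export
synthetic_world <- function(seed, n_groups = 8, genomes_per_group = 3,
                            basal_group = NULL, lgt_rate = 0.05,
                            loss_prob = 0.1, rate_noise_sd = 0.3,
                            trait_states = c("rod", "coccus")) {
  if (n_groups < 2) abort("`n_groups` must be at least 2")
  if (genomes_per_group < 1) abort("`genomes_per_group` must be at least 1")
  if (lgt_rate < 0 || loss_prob < 0 || loss_prob > 1 || rate_noise_sd < 0) {
    abort("rates must be non-negative (and loss_prob in [0, 1])")
  }
  groups <- sprintf("G%02d", seq_len(n_groups))
  basal_group <- basal_group %||% groups[1]
  if (!basal_group %in% groups) abort("`basal_group` must be one of the groups")
  genomes <- lapply(groups, function(g) {
    sprintf("%sg%02d", g, seq_len(genomes_per_group))
  })
  names(genomes) <- groups
  dw <- 0.3    # within-group depth
  tree <- withr::with_seed(seed, {
    basal <- subtree_nwk(genomes[[basal_group]], dw)
    rest_groups <- setdiff(groups, basal_group)
    if (length(rest_groups) == 1) {
      rest <- subtree_nwk(genomes[[rest_groups]], dw)
      rest_str <- paste0(rest$str, ":", format(1 - dw + rest$extra,
                                               digits = 15))
    } else {
      # the non-basal groups radiate on a coalescent backbone that hangs
      # from a distinct stem, so the basal split clearly predates it
      stem <- 0.25
      backbone <- scale_to_depth(
        ape::rcoal(length(rest_groups), tip.label = rest_groups),
        1 - dw - stem
      )
      nwk <- sub(";$", "", ape::write.tree(backbone))
      for (g in rest_groups) {
        nwk <- graft_nwk(nwk, g, subtree_nwk(genomes[[g]], dw))
      }
      rest_str <- paste0(nwk, ":", format(stem, digits = 15))
    }
    basal_str <- paste0(basal$str, ":",
                        format(1 - dw + basal$extra, digits = 15))
    ape::read.tree(text = paste0("(", basal_str, ",", rest_str, ");"))
  })
  structure(
    list(
      seed = seed,
      groups = tibble(
        genome_id = unlist(genomes, use.names = FALSE),
        group = rep(groups, lengths(genomes))
      ),
      basal_group = basal_group,
      species_tree = tree,
      lgt_rate = lgt_rate,
      loss_prob = loss_prob,
      rate_noise_sd = rate_noise_sd,
      trait_states = trait_states,
      root_state = trait_states[1]
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world (seed %d): %d groups x %d genomes, basal group %s\n",
    x$seed, dplyr::n_distinct(x$groups$group),
    sum(x$groups$group == x$basal_group), x$basal_group))
  cat(sprintf("lgt_rate = %g, loss_prob = %g, rate_noise_sd = %g\n",
              x$lgt_rate, x$loss_prob, x$rate_noise_sd))
  invisible(x)
}

# graft a new tip onto the terminal branch of `where_tip`;
# `position` = distance from the tip end, `tip_length` = new tip's branch
bind_tip <- function(tree, label, where_tip, position, tip_length) {
  n <- length(tree$tip.label)
  tip_idx <- match(where_tip, tree$tip.label)
  target <- which(tree$edge[, 2] == tip_idx)
  l <- tree$edge.length[target]
  if (position < 0 || position > l) abort("graft position outside the branch")
  e <- tree$edge
  e[e > n] <- e[e > n] + 1L
  new_tip <- n + 1L
  new_node <- n + tree$Nnode + 2L
  par <- e[target, 1]
  e[target, ] <- c(par, new_node)
  edge2 <- rbind(e, c(new_node, tip_idx), c(new_node, new_tip))
  len2 <- c(replace(tree$edge.length, target, l - position),
            position, tip_length)
  out <- list(edge = edge2, edge.length = len2,
              tip.label = c(tree$tip.label, label),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

#' Simulate gene trees from a synthetic world
#'
#' Each gene tree starts as the species history restricted to the genomes
#' that retain the gene (each genome loses it independently with probability
#' `loss_prob`; trees reduced below 3 leaves are redrawn and counted). A
#' Poisson number of lateral transfers (`lgt_rate` x branch count) is then
#' applied as topology-only subtree-prune-regraft moves: the donor leaf is
#' pruned and regrafted as the sister of a random recipient leaf, halfway
#' down the recipient's terminal branch, adopting the recipient's divergence
#' time. Finally every branch length is multiplied by i.i.d. lognormal
#' noise with log-sd `rate_noise_sd`.
#'
#' @param world A [synthetic_world()] object.
#' @param n_trees Number of gene trees (>= 1).
#' @param seed Seed; defaults to the world's seed (same world, same trees).
#' @return A list with `trees` (named list of rooted `phylo`, ids
#'   `T0001, ...`), `events` (tibble `tree_id`, `donor`, `recipient`) and
#'   `n_regenerated` (trees redrawn for falling below 3 leaves).
#' @export
simulate_gene_trees <- function(world, n_trees, seed = world$seed) {
  if (!inherits(world, "synthetic_world")) {
    abort("`world` must come from synthetic_world()")
  }
  if (n_trees < 1) abort("`n_trees` must be at least 1")
  species <- world$species_tree
  labels <- species$tip.label
  withr::with_seed(seed, {
    trees <- vector("list", n_trees)
    events <- list()
    n_regen <- 0L
    for (i in seq_len(n_trees)) {
      tree_id <- sprintf("T%04d", i)
      repeat {
        lost <- runif(length(labels)) < world$loss_prob
        if (sum(!lost) >= 3) break
        n_regen <- n_regen + 1L
      }
      tr <- if (any(lost)) ape::drop.tip(species, labels[lost]) else species
      n_ev <- rpois(1, world$lgt_rate * nrow(tr$edge))
      for (ev in seq_len(n_ev)) {
        if (length(tr$tip.label) < 4) break
        pair <- sample(tr$tip.label, 2)
        donor <- pair[1]
        recipient <- pair[2]
        tr <- ape::drop.tip(tr, donor)
        redge <- which(tr$edge[, 2] == match(recipient, tr$tip.label))
        half <- tr$edge.length[redge] / 2
        tr <- bind_tip(tr, donor, recipient, position = half,
                       tip_length = half)
        events[[length(events) + 1]] <- tibble(
          tree_id = tree_id, donor = donor, recipient = recipient
        )
      }
      if (world$rate_noise_sd > 0) {
        tr$edge.length <- tr$edge.length *
          rlnorm(length(tr$edge.length), 0, world$rate_noise_sd)
      }
      trees[[i]] <- tr
    }
    names(trees) <- sprintf("T%04d", seq_len(n_trees))
    list(
      trees = trees,
      events = if (length(events) > 0) dplyr::bind_rows(events) else
        tibble(tree_id = character(), donor = character(),
               recipient = character()),
      n_regenerated = n_regen
    )
  })
}

#' Evolve a discrete trait along a rooted tree
#'
#' The planted root state changes along each branch with probability
#' `1 - exp(-change_rate * t)`, switching to a uniformly random other state.
#' Used to plant a recoverable root state for ancestral-state tests.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param states Character state space.
#' @param root_state Planted state at the root.
#' @param change_rate Per-unit-length change rate. Default 0.3.
#' @param seed Integer seed.
#' @return Named character vector of tip states.
#' @export
simulate_trait_states <- function(tree, states, root_state,
                                  change_rate = 0.3, seed) {
  if (!root_state %in% states) abort("`root_state` must be in `states`")
  withr::with_seed(seed, {
    ntip <- length(tree$tip.label)
    state <- rep(NA_character_, ntip + tree$Nnode)
    state[ntip + 1L] <- root_state
    eo <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      s <- state[eo$edge[k, 1]]
      if (runif(1) < 1 - exp(-change_rate * eo$edge.length[k])) {
        s <- sample(setdiff(states, s), 1)
      }
      state[eo$edge[k, 2]] <- s
    }
    setNames(state[seq_len(ntip)], tree$tip.label)
  })
}

#' Simulate a planted-cluster protein similarity graph
#'
#' Sequences are partitioned into planted clusters. Within-cluster pairs are
#' connected with probability `p_in` and identities drawn from
#' `Normal(identity_in_mean, identity_sd)` (clipped to \[0, 100\]) with
#' passing e-values; between-cluster pairs with probability `p_out`,
#' identities around `identity_out_mean` and failing e-values. With the
#' defaults, between-cluster edges fall below both the 25% identity and the
#' 1e-10 e-value thresholds, so thresholded clustering should recover the
#' planted partition.
#'
#' @param cluster_sizes Integer vector of planted cluster sizes.
#' @param p_in,p_out Edge probabilities within/between clusters.
#' @param identity_in_mean,identity_out_mean,identity_sd Identity
#'   distribution parameters (percent).
#' @param seed Integer seed.
#' @return A list with `edges` (tibble `seq_a`, `seq_b`, `global_identity`,
#'   `e_value`) and `partition` (tibble `sequence_id`, `cluster`).
#' @export
simulate_similarity_graph <- function(cluster_sizes, p_in = 0.9,
                                      p_out = 0.05, identity_in_mean = 60,
                                      identity_out_mean = 15,
                                      identity_sd = 5, seed = 1) {
  n <- sum(cluster_sizes)
  ids <- sprintf("seq%04d", seq_len(n))
  cluster <- rep(seq_along(cluster_sizes), cluster_sizes)
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    same <- cluster[pairs[, 1]] == cluster[pairs[, 2]]
    keep <- runif(nrow(pairs)) < ifelse(same, p_in, p_out)
    pairs <- pairs[keep, , drop = FALSE]
    same <- same[keep]
    identity <- pmin(pmax(rnorm(
      nrow(pairs),
      ifelse(same, identity_in_mean, identity_out_mean),
      identity_sd
    ), 0), 100)
    e_value <- ifelse(same,
                      10^-runif(nrow(pairs), 20, 50),
                      10^-runif(nrow(pairs), 0, 9))
    list(
      edges = tibble(
        seq_a = ids[pairs[, 1]],
        seq_b = ids[pairs[, 2]],
        global_identity = identity,
        e_value = e_value
      ),
      partition = tibble(sequence_id = ids, cluster = cluster)
    )
  })
}

#' Simulate a presence matrix with planted universal families
#'
#' Each family's presence is drawn per genome as a Bernoulli with the
#' family's profile probability; families with profile exactly 1 are
#' present in every genome and form the planted universal set.
#'
#' @param n_families Number of families.
#' @param groups Group sizes: a data frame with columns `group`,
#'   `n_genomes`, or a named integer vector.
#' @param presence_profile Per-family presence probability, recycled to
#'   `n_families`. Default 0.6.
#' @param seed Integer seed.
#' @return A list with `presence` (tibble `family_id`, `group`,
#'   `genomes_with_family`, `genomes_in_group`) and `planted_universal`
#'   (family ids with profile 1).
#' @export
simulate_presence_matrix <- function(n_families, groups,
                                     presence_profile = 0.6, seed = 1) {
  if (is.data.frame(groups)) {
    check_columns(groups, c("group", "n_genomes"), "groups")
    sizes <- setNames(groups$n_genomes, groups$group)
  } else {
    sizes <- groups
  }
  prof <- rep_len(presence_profile, n_families)
  fam_ids <- sprintf("F%05d", seq_len(n_families))
  withr::with_seed(seed, {
    presence <- tidyr::expand_grid(
      family_id = fam_ids, group = names(sizes)
    ) |>
      dplyr::mutate(
        genomes_in_group = unname(sizes[.data$group]),
        genomes_with_family = rbinom(
          dplyr::n(), .data$genomes_in_group,
          prof[match(.data$family_id, fam_ids)]
        )
      ) |>
      dplyr::select("family_id", "group", "genomes_with_family",
                    "genomes_in_group")
    list(presence = presence, planted_universal = fam_ids[prof == 1])
  })
}

#' Simulate a reaction universe with a planted minimal completing set
#'
#' The core network is a connected chain from a seed compound; a subset of
#' the chain's intermediates are target metabolites, so the core alone
#' produces `n_targets - planted_set_size` of the targets. Each remaining
#' target is producible only through one reaction of the planted candidate
#' set; decoy candidates produce non-target compounds and can never
#' complete a missing target. Scores are drawn so planted reactions carry
#' high taxonomic-distribution scores and decoys low ones.
#'
#' Defaults mirror the scale of a conserved-core analysis: 57 universal
#' targets of which 48 are producible by the core's 121 reactions, and a
#' 9-reaction planted completing set.
#'
#' @param n_core Number of core chain reactions. Default 121.
#' @param n_candidates Number of candidate reactions (planted + decoys).
#'   Default 40.
#' @param n_targets Number of target metabolites. Default 57.
#' @param planted_set_size Size of the planted completing set. Default 9.
#' @param seed Integer seed.
#' @return A list with parsed reaction tibbles `core` and `candidates`
#'   (each with an `encoding_families` list-column), `targets` (tibble
#'   `compound_id`, `category`), `scores` (tibble `reaction_id`, `score`)
#'   and `planted` (the planted candidate reaction ids).
#' @export
simulate_reaction_universe <- function(n_core = 121, n_candidates = 40,
                                       n_targets = 57, planted_set_size = 9,
                                       seed = 1) {
  if (planted_set_size > n_candidates) {
    abort("`planted_set_size` cannot exceed `n_candidates`")
  }
  if (planted_set_size > n_targets) {
    abort("`planted_set_size` cannot exceed `n_targets`")
  }
  n_chain_targets <- n_targets - planted_set_size
  if (n_chain_targets > n_core) {
    abort("core chain too short to produce the non-planted targets")
  }
  categories <- c(rep("amino acid", 20), rep("DNA base", 4),
                  rep("RNA base", 4), rep("cofactor", 8),
                  "lipid precursor", rep("charged tRNA", 20))
  categories <- rep_len(categories, n_targets)
  target_ids <- sprintf("T%03d", seq_len(n_targets))
  withr::with_seed(seed, {
    chain_targets <- target_ids[seq_len(n_chain_targets)]
    missing_targets <- setdiff(target_ids, chain_targets)
    # chain compounds; a random subset of positions are the chain targets
    chain <- sprintf("X%03d", seq_len(n_core))
    tpos <- sort(sample(n_core, n_chain_targets))
    chain[tpos] <- chain_targets
    nodes <- c("S001", chain)
    core <- tibble(
      reaction_id = sprintf("CORE%03d", seq_len(n_core)),
      substrates = lapply(seq_len(n_core),
                          function(i) setNames(1L, nodes[i])),
      products = lapply(seq_len(n_core),
                        function(i) setNames(1L, nodes[i + 1])),
      reversible = FALSE
    )
    n_decoys <- n_candidates - planted_set_size
    planted_ids <- sprintf("CANDP%02d", seq_len(planted_set_size))
    decoy_ids <- sprintf("CANDD%02d", seq_len(max(n_decoys, 0)))
    planted <- tibble(
      reaction_id = planted_ids,
      substrates = lapply(sample(nodes, planted_set_size, replace = TRUE),
                          function(s) setNames(1L, s)),
      products = lapply(missing_targets, function(t) setNames(1L, t)),
      reversible = FALSE
    )
    decoys <- tibble(
      reaction_id = decoy_ids,
      substrates = lapply(sample(nodes, n_decoys, replace = TRUE),
                          function(s) setNames(1L, s)),
      products = lapply(seq_len(n_decoys),
                        function(i) setNames(1L, sprintf("D%03d", i))),
      reversible = FALSE
    )
    candidates <- dplyr::bind_rows(planted, decoys)
    core$equation <- format_reaction(core)
    candidates$equation <- format_reaction(candidates)
    core$encoding_families <- as.list(paste0("fam_", core$reaction_id))
    candidates$encoding_families <-
      as.list(paste0("fam_", candidates$reaction_id))
    scores <- tibble(
      reaction_id = c(planted_ids, decoy_ids),
      score = c(sample(15:25, planted_set_size, replace = TRUE),
                sample(1:10, max(n_decoys, 0), replace = TRUE))
    )
    list(core = core, candidates = candidates,
         targets = tibble(compound_id = target_ids, category = categories),
         scores = scores, planted = planted_ids)
  })
}
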