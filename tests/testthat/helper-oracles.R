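# Independent brute-force oracles used to validate the analytical
# implementations. These deliberately use naive algorithms (grid search,
# exhaustive enumeration, repeated-scan fixed points) rather than the
# closed forms or recursions under test.

# ---- MAD rooting: grid search over 1000 root positions per branch --------
# Ancestors of same-side leaf pairs are taken from ape::mrca on an
# explicitly re-oriented tree; sides are derived from the distance matrix.
mad_grid_oracle <- function(tree, n_grid = 1000) {
  u <- ape::unroot(tree)
  ntip <- length(u$tip.label)
  D <- ape::dist.nodes(u)
  best_mad <- Inf
  best_edge <- NA_integer_
  for (e in seq_len(nrow(u$edge))) {
    p <- u$edge[e, 1]
    cc <- u$edge[e, 2]
    l <- u$edge.length[e]
    side <- abs(D[p, seq_len(ntip)] - (l + D[cc, seq_len(ntip)])) < 1e-9
    anchor <- if (cc > ntip) cc else p
    ru <- ape::root(u, node = anchor, resolve.root = FALSE)
    DN <- ape::dist.nodes(ru)
    M <- ape::mrca(ru)
    idx <- match(u$tip.label, ru$tip.label)
    fixed_sq <- c()
    span_i <- c()
    span_d <- c()
    for (i in 1:(ntip - 1)) {
      for (j in (i + 1):ntip) {
        dij <- D[i, j]
        if (dij == 0) next
        if (side[i] != side[j]) {
          ci <- if (side[i]) i else j   # the child-side leaf
          span_i <- c(span_i, D[cc, ci])
          span_d <- c(span_d, dij)
        } else {
          anc <- M[idx[i], idx[j]]
          fixed_sq <- c(fixed_sq, (2 * DN[anc, idx[i]] / dij - 1)^2)
        }
      }
    }
    xs <- seq(0, l, length.out = n_grid)
    npairs <- length(fixed_sq) + length(span_i)
    for (x in xs) {
      ss <- sum(fixed_sq) + sum((2 * (span_i + x) / span_d - 1)^2)
      m <- sqrt(ss / npairs)
      if (m < best_mad) {
        best_mad <- m
        best_edge <- e
      }
    }
  }
  list(mad = best_mad, edge = best_edge)
}

# ---- network expansion: dead-simple repeated-scan fixed point ------------
scope_oracle <- function(reactions, seeds) {
  set <- unique(as.character(seeds))
  repeat {
    added <- FALSE
    for (i in seq_len(nrow(reactions))) {
      subs <- names(reactions$substrates[[i]])
      prods <- names(reactions$products[[i]])
      if (all(subs %in% set) && !all(prods %in% set)) {
        set <- union(set, prods)
        added <- TRUE
      }
      if (isTRUE(reactions$reversible[i]) &&
          all(prods %in% set) && !all(subs %in% set)) {
        set <- union(set, subs)
        added <- TRUE
      }
    }
    if (!added) break
  }
  sort(set)
}

# random small reaction networks for scope tests
random_reactions <- function(n_rxn = 20, n_compounds = 15, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("C%02d", seq_len(n_compounds))
    subs <- list()
    prods <- list()
    for (i in seq_len(n_rxn)) {
      k <- sample(2:4, 1)
      picks <- sample(ids, k)
      ns <- sample(seq_len(k - 1), 1)
      subs[[i]] <- setNames(rep(1L, ns), picks[seq_len(ns)])
      prods[[i]] <- setNames(rep(1L, k - ns), picks[(ns + 1):k])
    }
    tibble::tibble(
      reaction_id = sprintf("R%02d", seq_len(n_rxn)),
      substrates = subs,
      products = prods,
      reversible = runif(n_rxn) < 0.3
    )
  })
}

# ---- reduction: exhaustive search over candidate subsets -----------------
# In produced_by_any mode feasibility is a set-cover question: the selected
# candidates' products must cover the targets the core cannot produce.
min_cover_oracle <- function(core, candidates, targets) {
  target_ids <- if (is.data.frame(targets)) targets$compound_id else targets
  core_prod <- unique(unlist(lapply(seq_len(nrow(core)), function(i) {
    p <- names(core$products[[i]])
    if (isTRUE(core$reversible[i])) c(p, names(core$substrates[[i]])) else p
  })))
  need <- setdiff(target_ids, core_prod)
  cand_prod <- lapply(seq_len(nrow(candidates)), function(i) {
    p <- names(candidates$products[[i]])
    if (isTRUE(candidates$reversible[i])) {
      c(p, names(candidates$substrates[[i]]))
    } else {
      p
    }
  })
  n <- nrow(candidates)
  best_size <- Inf
  best_sets <- list()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) > best_size) next
    covered <- unique(unlist(cand_prod[idx]))
    if (all(need %in% covered)) {
      if (length(idx) < best_size) {
        best_size <- length(idx)
        best_sets <- list(sort(candidates$reaction_id[idx]))
      } else if (length(idx) == best_size) {
        best_sets[[length(best_sets) + 1]] <-
          sort(candidates$reaction_id[idx])
      }
    }
  }
  list(size = best_size, sets = best_sets)
}

# ---- Wilcoxon: exact enumeration by bitmask ------------------------------
wilcoxon_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    w <- sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
    if (w <= v + 1e-9) count <- count + 1L
  }
  count / 2^n
}

# ---- KS statistic: ECDF sup over pooled points ---------------------------
ks_d_oracle <- function(x, y) {
  pts <- sort(c(x, y))
  max(abs(stats::ecdf(x)(pts) - stats::ecdf(y)(pts)))
}

# ---- F81 root posterior: exhaustive summation over node states -----------
f81_brute_oracle <- function(tree, tip_states, states, pi) {
  k <- length(states)
  beta <- 1 / (1 - sum(pi^2))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  edges <- tree$edge
  lens <- tree$edge.length
  ptrans <- function(i, j, t) {
    pi[j] + ((i == j) - pi[j]) * exp(-beta * t)
  }
  obs <- tip_states[tree$tip.label]
  # free nodes: all internals plus unknown tips; root is ntip+1
  free <- c(seq_len(ntip)[is.na(obs)], (ntip + 1):nn)
  post <- setNames(numeric(k), states)
  assign_states <- rep(NA_integer_, nn)
  assign_states[seq_len(ntip)] <- match(obs, states)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(free)))
  for (g in seq_len(nrow(grid))) {
    st <- assign_states
    st[free] <- as.integer(grid[g, ])
    prob <- pi[st[ntip + 1]]
    for (e in seq_len(nrow(edges))) {
      prob <- prob * ptrans(st[edges[e, 1]], st[edges[e, 2]], lens[e])
    }
    post[st[ntip + 1]] <- post[st[ntip + 1]] + prob
  }
  post / sum(post)
}

# ---- dense base-R MCL (no sparse matrices) -------------------------------
mcl_dense_oracle <- function(adj, inflation = 2, max_iter = 200,
                             tol = 1e-6) {
  n <- nrow(adj)
  diag(adj) <- apply(adj, 2, function(col) if (any(col > 0)) max(col) else 1)
  norm <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- norm(adj)
  for (it in seq_len(max_iter)) {
    M2 <- norm((M %*% M)^inflation)
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      break
    }
    M <- M2
  }
  S <- (M > 1e-7) | t(M > 1e-7)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(apply(S[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

# partitions as canonical sets of member sets, for label-free comparison
partition_sets <- function(members, labels) {
  unname(lapply(split(labels, members), function(x) sort(x))) |>
    (\(x) x[order(vapply(x, `[`, "", 1))])()
}
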