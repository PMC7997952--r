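test_that("the species history is ultrametric with a basal clade", {
  w <- synthetic_world(seed = 42)
  tr <- w$species_tree
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(sort(tr$tip.label), sort(w$groups$genome_id))
  # every group is monophyletic; the basal group attaches at the root
  for (g in unique(w$groups$group)) {
    expect_true(ape::is.monophyletic(
      tr, w$groups$genome_id[w$groups$group == g]))
  }
  basal_tips <- w$groups$genome_id[w$groups$group == w$basal_group]
  basal_mrca <- ape::getMRCA(tr, basal_tips)
  root <- length(tr$tip.label) + 1L
  expect_equal(tr$edge[tr$edge[, 2] == basal_mrca, 1][1], root)
})

test_that("gene trees are deterministic and collapse to the species tree", {
  w <- synthetic_world(seed = 7, lgt_rate = 0, loss_prob = 0,
                       rate_noise_sd = 0)
  gt <- simulate_gene_trees(w, 5)
  # without loss, transfer or noise every tree is the species history
  for (tr in gt$trees) {
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(w$species_tree))), 0)
    expect_equal(sort(tr$tip.label), sort(w$species_tree$tip.label))
  }
  expect_equal(nrow(gt$events), 0)

  # same seed, byte-identical output
  w2 <- synthetic_world(seed = 11)
  a <- simulate_gene_trees(w2, 10)
  b <- simulate_gene_trees(w2, 10)
  expect_identical(lapply(a$trees, ape::write.tree),
                   lapply(b$trees, ape::write.tree))
  expect_identical(a$events, b$events)
})

test_that("transfer counts follow the Poisson expectation", {
  w <- synthetic_world(seed = 5, lgt_rate = 0.02, loss_prob = 0,
                       rate_noise_sd = 0)
  n_branches <- nrow(w$species_tree$edge)
  gt <- simulate_gene_trees(w, 1000)
  lambda <- 0.02 * n_branches * 1000
  expect_lt(abs(nrow(gt$events) - lambda), 3 * sqrt(lambda))
  # transfers move the donor next to the recipient
  ev <- gt$events[1, ]
  tr <- gt$trees[[ev$tree_id]]
  expect_true(all(c(ev$donor, ev$recipient) %in% tr$tip.label))
})

test_that("similarity graphs reproduce the planted partition structure", {
  sim <- simulate_similarity_graph(c(4, 5), p_in = 1, p_out = 0, seed = 2)
  g <- build_similarity_graph(sim$edges)
  comp <- igraph::components(g)$membership
  expect_equal(
    partition_sets(comp, names(comp)),
    partition_sets(sim$partition$cluster, sim$partition$sequence_id)
  )
  # determinism
  expect_identical(sim$edges,
                   simulate_similarity_graph(c(4, 5), p_in = 1, p_out = 0,
                                             seed = 2)$edges)
  # between-cluster e-values always fail the 1e-10 threshold
  sim2 <- simulate_similarity_graph(c(4, 5), p_in = 1, p_out = 1, seed = 3)
  between <- sim2$edges$e_value[
    sim2$partition$cluster[match(sim2$edges$seq_a,
                                 sim2$partition$sequence_id)] !=
      sim2$partition$cluster[match(sim2$edges$seq_b,
                                   sim2$partition$sequence_id)]]
  expect_true(all(between > 1e-10))
})

test_that("presence simulation plants recoverable universal families", {
  groups <- tibble::tibble(group = c("A", "B", "C"), n_genomes = c(5L, 4L, 6L))
  # non-planted profile low enough that chance universality (at least one
  # carrier in every group) is improbable
  prof <- c(1, 1, rep(0.05, 18))
  sim <- simulate_presence_matrix(20, groups, prof, seed = 8)
  expect_equal(sim$planted_universal, c("F00001", "F00002"))
  u <- universal_families(sim$presence)
  expect_setequal(u$family_id[u$universal], sim$planted_universal)
  # all-ones profile: everything universal with coverage 1
  sim2 <- simulate_presence_matrix(5, groups, 1, seed = 8)
  u2 <- universal_families(sim2$presence)
  expect_true(all(u2$universal))
  expect_true(all(u2$mean_coverage == 1))
  # determinism
  expect_identical(sim$presence,
                   simulate_presence_matrix(20, groups, prof,
                                            seed = 8)$presence)
})

test_that("reaction universes respect their planted construction", {
  u <- simulate_reaction_universe(seed = 21)   # study-scale defaults
  pt <- producible_targets(u$core, u$targets)
  expect_equal(sum(pt$producible), 48)
  expect_equal(nrow(pt), 57)
  all_rx <- dplyr::bind_rows(u$core, u$candidates)
  expect_true(all(producible_targets(all_rx, u$targets)$producible))
  expect_length(u$planted, 9)
  # the core is one connected chain
  net <- build_reaction_network(u$core)
  expect_equal(nrow(net$components), 1)
  # decoys never produce a target
  decoys <- u$candidates[!u$candidates$reaction_id %in% u$planted, ]
  decoy_products <- unlist(lapply(decoys$products, names))
  expect_length(intersect(decoy_products, u$targets$compound_id), 0)
  # determinism and infeasibility guards
  expect_identical(u$scores, simulate_reaction_universe(seed = 21)$scores)
  expect_error(simulate_reaction_universe(n_candidates = 3,
                                          planted_set_size = 5), "exceed")
  expect_error(simulate_reaction_universe(n_core = 10, n_targets = 30,
                                          planted_set_size = 2), "chain")
})

test_that("generated artifacts round-trip through the writers and readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_similarity_graph(c(3, 4), seed = 13)
  write_edge_table(sim$edges, file.path(dir, "edges.tsv"))
  expect_equal(read_edge_table(file.path(dir, "edges.tsv")), sim$edges)

  groups <- tibble::tibble(group = c("A", "B"), n_genomes = c(3L, 3L))
  pm <- simulate_presence_matrix(6, groups, 0.5, seed = 13)
  write_presence_table(pm$presence, file.path(dir, "presence.tsv"))
  expect_equal(read_presence_table(file.path(dir, "presence.tsv")),
               pm$presence)

  u <- simulate_reaction_universe(n_core = 10, n_candidates = 5,
                                  n_targets = 8, planted_set_size = 2,
                                  seed = 13)
  write_reaction_table(u$core, file.path(dir, "core.tsv"))
  back <- read_reaction_table(file.path(dir, "core.tsv"))
  reparsed <- parse_reactions(back)$reactions
  expect_equal(reparsed$substrates, u$core$substrates)
  expect_equal(reparsed$products, u$core$products)

  fams <- tibble::tibble(family_id = "f1", sequence_id = c("s1", "s2"),
                         genome_id = c("g1", "g2"))
  write_family_table(fams, file.path(dir, "fams.tsv"))
  expect_equal(read_family_table(file.path(dir, "fams.tsv")), fams)

  w <- synthetic_world(seed = 13, n_groups = 4, genomes_per_group = 2)
  gt <- simulate_gene_trees(w, 2)
  ape::write.tree(gt$trees[[1]], file.path(dir, "t1.nwk"))
  t1 <- ape::read.tree(file.path(dir, "t1.nwk"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1),
                                         ape::unroot(gt$trees[[1]]))), 0)
  expect_equal(sort(t1$tip.label), sort(gt$trees[[1]]$tip.label))
})
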