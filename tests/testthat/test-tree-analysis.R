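test_that("MAD roots a clocklike quartet on the bisecting branch", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  mr <- mad_root(tree)
  expect_lte(mr$mad_value, 1e-10)
  expect_false(mr$is_ambiguous)
  # the best branch is the internal one: both endpoints are internal nodes
  ntip <- 4
  best <- mr$table[1, ]
  expect_true(best$parent > ntip && best$child > ntip)
  # rooted tree is ultrametric again
  rt <- root_tree(mr)
  d <- root_to_tip(rt, "branch_length")
  expect_true(all(abs(d$distance - d$distance[1]) < 1e-12))
})

test_that("MAD agrees with the grid-search oracle on random trees", {
  for (s in 1:20) {
    tree <- withr::with_seed(s, {
      t <- ape::rtree(8)
      t$edge.length <- stats::rexp(nrow(t$edge), 10)
      t
    })
    mr <- mad_root(tree)
    oracle <- mad_grid_oracle(tree, n_grid = 400)
    expect_lt(abs(mr$mad_value - oracle$mad), 1e-4)
  }
})

test_that("MAD is invariant to leaf relabeling and input rooting", {
  tree <- withr::with_seed(7, {
    t <- ape::rtree(10)
    t$edge.length <- stats::rexp(nrow(t$edge), 5)
    t
  })
  mr <- mad_root(tree)
  # relabel leaves: same minimal deviation
  t2 <- tree
  t2$tip.label <- rev(tree$tip.label)
  expect_equal(mad_root(t2)$mad_value, mr$mad_value, tolerance = 1e-12)
  # reroot the input representation elsewhere: same result
  t3 <- ape::root(tree, outgroup = tree$tip.label[3], resolve.root = TRUE)
  expect_equal(mad_root(t3)$mad_value, mr$mad_value, tolerance = 1e-9)
  # and the same root-to-tip distances from the inferred root
  d1 <- root_to_tip(root_tree(mr), "branch_length")
  d3 <- root_to_tip(root_tree(mad_root(t3)), "branch_length")
  expect_equal(d3$distance[match(d1$leaf, d3$leaf)], d1$distance,
               tolerance = 1e-9)
})

test_that("root ambiguity is flagged on symmetric trees and filtered", {
  # a 3-leaf star with equal branches: all three candidate roots tie
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  mr <- mad_root(star)
  expect_true(mr$is_ambiguous)
  expect_equal(mr$ambiguity_index, 1, tolerance = 1e-12)
  # a clearly asymmetric clocklike tree is unambiguous
  quartet <- mad_root(ape::read.tree(text = "((a:1,b:1):2,(c:3,d:3):0.01);"))
  expect_false(quartet$is_ambiguous)
  kept <- suppressMessages(filter_ambiguous(list(mr, quartet, mr)))
  expect_length(kept, 1)
  expect_equal(attr(kept, "n_ambiguous"), 2)
})

test_that("MAD recovers the true root of strict-clock trees", {
  ok <- vapply(1:200, function(s) {
    tree <- withr::with_seed(s, ape::rcoal(16))
    mr <- mad_root(tree)
    if (mr$mad_value > 1e-10) return(FALSE)
    d <- root_to_tip(root_tree(mr), "branch_length")$distance
    max(abs(d - d[1])) < 1e-8   # re-rooted tree is ultrametric again
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate and undersized trees are rejected", {
  flat <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  expect_error(mad_root(flat), "degenerate")
  pair <- ape::read.tree(text = "(a:1,b:1);")
  expect_error(mad_root(pair), "at least 3")
  nolen <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(mad_root(nolen), "branch lengths")
})

test_that("root-to-tip distances normalize per tree and metric", {
  balanced <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  d <- root_to_tip(balanced, "branch_length")
  expect_true(all(d$normalized_distance == 1))

  caterpillar <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:1);")
  nd <- root_to_tip(caterpillar, "node_depth")
  expect_equal(setNames(nd$distance, nd$leaf)[c("a", "b", "c", "d")],
               c(a = 3, b = 3, c = 2, d = 1))
  expect_equal(max(nd$normalized_distance), 1)

  # branch-length normalization is scale invariant
  scaled <- caterpillar
  scaled$edge.length <- scaled$edge.length * 7.3
  expect_equal(root_to_tip(scaled, "branch_length")$normalized_distance,
               root_to_tip(caterpillar, "branch_length")$normalized_distance)

  zero <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  expect_error(root_to_tip(zero, "branch_length"), "zero")
})

test_that("group divergence picks each group's closest representative", {
  tree <- ape::read.tree(text = "(((a1:1,a2:3):1,b1:1):1,b2:5);")
  d <- root_to_tip(tree, "branch_length")
  d$tree_id <- "T1"
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rec <- group_divergence(d, groups)
  # hand values: a1 = 3, a2 = 5, b1 = 2, b2 = 5; max = 5
  expect_equal(rec$normalized_distance[rec$group == "A"], 3 / 5)
  expect_equal(rec$representative[rec$group == "A"], "a1")
  expect_equal(rec$normalized_distance[rec$group == "B"], 2 / 5)
  expect_equal(rec$representative[rec$group == "B"], "b1")
  # a group absent from the tree yields no record
  rec2 <- group_divergence(d, c(groups, zz = "C"))
  expect_false("C" %in% rec2$group)
  # across-tree means
  d2 <- d
  d2$tree_id <- "T2"
  means <- divergence_means(group_divergence(dplyr::bind_rows(d, d2),
                                             groups))
  expect_equal(means$n_trees, c(2L, 2L))
})

test_that("sister diversity scores pure clades against their sisters", {
  tree <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,C1:1):1);")
  groups <- c(A1 = "A", A2 = "A", B1 = "B", C1 = "C")
  sd1 <- sister_diversity(tree, groups)
  expect_equal(sd1$score[sd1$group == "A"], 2L)   # sister holds B and C
  expect_equal(sd1$pure_clade_count[sd1$group == "A"], 1L)
  expect_equal(sd1$score[sd1$group == "B"], 1L)
  expect_equal(sd1$score[sd1$group == "C"], 1L)

  # two groups only: every score is 1
  g2 <- c(A1 = "A", A2 = "A", B1 = "B", C1 = "B")
  expect_true(all(sister_diversity(tree, g2)$score == 1L))

  # scattered group: two pure clades, the scores take the maximum
  tree2 <- ape::read.tree(
    text = "(((A1:1,B1:1):1,(A2:1,C1:1):1):1,D1:1);")
  g3 <- c(A1 = "A", B1 = "B", A2 = "A", C1 = "C", D1 = "D")
  sd2 <- sister_diversity(tree2, g3)
  expect_equal(sd2$pure_clade_count[sd2$group == "A"], 2L)
  expect_equal(sd2$score[sd2$group == "A"], 1L)
  expect_equal(sd2$score[sd2$group == "D"], 3L)   # sister holds A, B, C

  # single-group tree: no records
  expect_equal(nrow(sister_diversity(tree, c(A1 = "X", A2 = "X",
                                             B1 = "X", C1 = "X"))), 0)
})

test_that("sister diversity stays within [1, G-1] on random trees", {
  for (s in 1:20) {
    w <- synthetic_world(seed = s, n_groups = 5, genomes_per_group = 2)
    gt <- simulate_gene_trees(w, 3)
    for (tr in gt$trees) {
      mr <- mad_root(tr)
      sd <- sister_diversity(root_tree(mr), w$groups)
      G <- dplyr::n_distinct(w$groups$group[w$groups$genome_id %in%
                                              tr$tip.label])
      expect_true(all(sd$score >= 1 & sd$score <= G - 1))
    }
  }
})
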