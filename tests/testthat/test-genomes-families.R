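test_that("oxygen classification applies its three thresholds literally", {
  genomes <- tibble::tibble(
    genome_id = c("g_nohit", "g_hit", "g_short", "g_small"),
    phylum = "Firmicutes",
    protein_count = c(1500L, 1500L, 1500L, 900L)
  )
  hits <- tibble::tibble(
    genome_id = c("g_hit", "g_short"),
    percent_identity = c(30, 30),
    e_value = c(1e-20, 1e-20),
    aligned_length_aa = c(300L, 299L)
  )
  kept <- select_anaerobes(genomes, hits, min_proteins = 1000)
  # a qualifying hit marks the genome aerobic; 299 aa misses the cutoff;
  # a zero-hit genome is anaerobic; <=1000 proteins is excluded
  expect_setequal(kept$genome_id, c("g_nohit", "g_short"))
  expect_true(all(kept$oxygen_class == "anaerobic"))

  # boundary: identity and e-value are strict for classification
  hits2 <- tibble::tibble(
    genome_id = "g_hit",
    percent_identity = c(25, 26, 26),
    e_value = c(1e-20, 1e-10, 1e-11),
    aligned_length_aa = 300L
  )
  k1 <- select_anaerobes(genomes, hits2[1, ], min_proteins = 1000)
  expect_true("g_hit" %in% k1$genome_id)        # identity == 25 not > 25
  k2 <- select_anaerobes(genomes, hits2[2, ], min_proteins = 1000)
  expect_true("g_hit" %in% k2$genome_id)        # e == 1e-10 not < 1e-10
  k3 <- select_anaerobes(genomes, hits2[3, ], min_proteins = 1000)
  expect_false("g_hit" %in% k3$genome_id)

  expect_error(
    select_anaerobes(genomes, tibble::tibble(
      genome_id = "nope", percent_identity = 30, e_value = 0,
      aligned_length_aa = 400L
    )),
    "absent"
  )
})

test_that("group assignment splits the large phyla and pools rare ones", {
  genomes <- tibble::tibble(
    genome_id = sprintf("g%02d", 1:12),
    phylum = c(rep("Firmicutes", 2), rep("Proteobacteria", 2),
               rep("Bacteroidetes", 5), rep("Aquificae", 3)),
    class_name = c("Clostridia", "Bacilli", "Deltaproteobacteria",
                   "Gammaproteobacteria", rep(NA, 8)),
    species = c("f sp1", "f sp2", "p sp1", "p sp2",
                sprintf("b sp%d", 1:5), sprintf("a sp%d", 1:3))
  )
  out <- assign_groups(genomes)
  expect_equal(out$group[1:4],
               c("Clostridia", "Bacilli", "Deltaproteobacteria",
                 "Gammaproteobacteria"))
  expect_true(all(out$group[5:9] == "Bacteroidetes"))   # >= 5 species
  expect_true(all(out$group[10:12] == "Other Bacteria")) # < 5 species
  expect_equal(dplyr::n_distinct(out$group), 6)

  noclass <- genomes
  noclass$class_name[1] <- NA
  expect_error(assign_groups(noclass), "g01")
})

test_that("similarity graph thresholds, duplicate collapse and node set", {
  edges <- tibble::tibble(
    seq_a = c("a", "a", "b", "b", "c"),
    seq_b = c("b", "c", "c", "a", "d"),
    global_identity = c(25.0, 24.9, 30, 40, 50),
    e_value = c(1e-10, 1e-12, 1e-11, 1e-11, 1e-9)
  )
  g <- build_similarity_graph(edges)
  # 25.0/1e-10 retained (inclusive); 24.9 dropped despite good e-value;
  # duplicate a-b pair collapsed keeping max identity; 1e-9 dropped
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(g), 2)
  ab <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("a", "b"))]
  expect_equal(ab, 40)

  empty <- build_similarity_graph(edges[0, ])
  expect_equal(igraph::ecount(empty), 0)

  bad <- edges
  bad$global_identity[3] <- 101
  expect_error(build_similarity_graph(bad), "row")
  loop <- edges
  loop$seq_b[1] <- "a"
  expect_error(build_similarity_graph(loop), "self-edges")
})

test_that("MCL separates weakly bridged cliques and matches a dense oracle", {
  clique_edges <- function(members, w) {
    p <- t(utils::combn(members, 2))
    tibble::tibble(seq_a = p[, 1], seq_b = p[, 2],
                   global_identity = w, e_value = 1e-30)
  }
  # two 4-cliques, no bridge: components never merge
  e1 <- dplyr::bind_rows(clique_edges(paste0("x", 1:4), 50),
                         clique_edges(paste0("y", 1:4), 50))
  f1 <- mcl_cluster(build_similarity_graph(e1))
  expect_equal(dplyr::n_distinct(f1$family_id), 2)
  expect_true(attr(f1, "converged"))

  # two 5-cliques joined by one weak bridge: inflation severs the bridge
  e2 <- dplyr::bind_rows(
    clique_edges(paste0("x", 1:5), 50),
    clique_edges(paste0("y", 1:5), 50),
    tibble::tibble(seq_a = "x1", seq_b = "y1",
                   global_identity = 25, e_value = 1e-30)
  )
  g2 <- build_similarity_graph(e2)
  f2 <- mcl_cluster(g2, inflation = 2)
  expect_equal(dplyr::n_distinct(f2$family_id), 2)
  x_fams <- unique(f2$family_id[grepl("^x", f2$sequence_id)])
  expect_length(x_fams, 1)

  # agreement with an independent dense-matrix iteration
  adj <- as.matrix(igraph::as_adjacency_matrix(g2, attr = "weight"))
  oracle <- mcl_dense_oracle(adj)
  expect_equal(
    partition_sets(f2$family_id[match(rownames(adj), f2$sequence_id)],
                   rownames(adj)),
    partition_sets(oracle, rownames(adj))
  )

  # singleton node (all edges filtered) forms a singleton family
  e3 <- tibble::tibble(seq_a = "solo", seq_b = "other",
                       global_identity = 10, e_value = 1)
  f3 <- mcl_cluster(build_similarity_graph(e3))
  expect_equal(nrow(f3), 2)
  expect_equal(dplyr::n_distinct(f3$family_id), 2)
})

test_that("MCL partitions are true partitions and relabeling-invariant", {
  sim <- simulate_similarity_graph(c(4, 6, 5), seed = 17)
  g <- build_similarity_graph(sim$edges)
  fam <- mcl_cluster(g)
  # every node in exactly one family
  expect_setequal(fam$sequence_id, igraph::V(g)$name)
  expect_equal(anyDuplicated(fam$sequence_id), 0)
  # relabeling the nodes must not change the partition as sets
  perm <- withr::with_seed(5, sample(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  fam2 <- mcl_cluster(g2)
  expect_equal(
    partition_sets(fam$family_id, fam$sequence_id),
    partition_sets(fam2$family_id, fam2$sequence_id)
  )
})

test_that("MCL recovers planted partitions from simulated graphs", {
  recovered <- vapply(1:100, function(s) {
    sim <- simulate_similarity_graph(c(6, 6, 6), seed = s)
    fam <- mcl_cluster(build_similarity_graph(sim$edges))
    identical(
      partition_sets(fam$family_id, fam$sequence_id),
      partition_sets(sim$partition$cluster, sim$partition$sequence_id)
    )
  }, logical(1))
  expect_gte(mean(recovered), 0.99)
})

test_that("family filtering and the presence matrix match hand enumeration", {
  genomes <- tibble::tibble(
    genome_id = c("g1", "g2", "g3", "g4"),
    species = c("sp1", "sp2", "sp3", "sp3"),
    group = c("A", "A", "B", "B")
  )
  families <- tibble::tibble(
    family_id = c(rep("f1", 4), rep("f2", 4), rep("f3", 3)),
    sequence_id = sprintf("s%02d", 1:11),
    genome_id = c("g1", "g2", "g3", "g4",   # f1: 3 species, 4 genomes
                  "g1", "g1", "g3", "g4",   # f2: 2 species, 3 genomes
                  "g1", "g2", "g3")         # f3: 3 species, 3 genomes
  )
  out <- filter_families(families, genomes, min_species = 3, min_genomes = 4)
  expect_equal(unique(out$families$family_id), "f1")
  m <- out$presence
  expect_equal(m$genomes_with_family[m$group == "A"], 2L)
  expect_equal(m$genomes_with_family[m$group == "B"], 2L)
  expect_true(all(m$genomes_in_group == 2L))

  # inclusive thresholds: 3 species / 4 genomes is retained
  out2 <- filter_families(families, genomes, min_species = 3,
                          min_genomes = 3)
  expect_setequal(unique(out2$families$family_id), c("f1", "f3"))

  orphan <- families
  orphan$genome_id[1] <- "gX"
  expect_error(filter_families(orphan, genomes), "gX")
})

test_that("universality and mean coverage follow their definitions", {
  presence <- tibble::tibble(
    family_id = rep(c("f_all", "f_24", "f_half"), each = 2),
    group = rep(c("A", "B"), 3),
    genomes_with_family = c(4L, 4L, 4L, 0L, 4L, 2L),
    genomes_in_group = 4L
  )
  u <- universal_families(presence, coverage_threshold = 0.9)
  expect_true(u$universal[u$family_id == "f_all"])
  expect_false(u$universal[u$family_id == "f_24"])    # one group missed
  expect_equal(u$mean_coverage[u$family_id == "f_all"], 1.0)
  expect_equal(u$mean_coverage[u$family_id == "f_half"], 0.75)
  expect_false(u$high_coverage[u$family_id == "f_half"])

  # universal set shrinks (never grows) as groups are added
  extra <- dplyr::bind_rows(presence, tibble::tibble(
    family_id = c("f_all", "f_24", "f_half"), group = "C",
    genomes_with_family = c(1L, 1L, 0L), genomes_in_group = 3L
  ))
  u2 <- universal_families(extra)
  expect_true(all(u2$family_id[u2$universal] %in% u$family_id[u$universal]))

  bad <- presence
  bad$genomes_in_group[1] <- 0L
  expect_error(universal_families(bad), "at least one genome")
})

test_that("family annotation keeps best hits and reports ties", {
  families <- tibble::tibble(
    family_id = rep("f1", 4),
    sequence_id = c("s1", "s2", "s3", "s4")
  )
  hit <- function(q, cat, e = 1e-20, qc = 0.9, pid = 50, lr = 1) {
    tibble::tibble(query_id = q, subject_id = paste0("K_", cat),
                   e_value = e, query_coverage = qc,
                   percent_identity = pid, length_ratio = lr,
                   category = cat)
  }
  # unanimous annotation
  h1 <- dplyr::bind_rows(hit("s1", "Translation"), hit("s2", "Translation"),
                         hit("s3", "Translation"))
  expect_equal(annotate_families(families, h1)$category, "Translation")

  # 2-2 frequency tie: both categories reported
  h2 <- dplyr::bind_rows(hit("s1", "Translation"), hit("s2", "Translation"),
                         hit("s3", "tRNA charging"),
                         hit("s4", "tRNA charging"))
  expect_setequal(annotate_families(families, h2)$category,
                  c("Translation", "tRNA charging"))

  # coverage below 0.8 is ignored regardless of e-value
  h3 <- hit("s1", "Translation", e = 0, qc = 0.79)
  expect_equal(nrow(annotate_families(families, h3)), 0)

  # best-hit tie-breaking: lower e-value wins over higher coverage
  h4 <- dplyr::bind_rows(hit("s1", "A", e = 1e-30, qc = 0.85),
                         hit("s1", "B", e = 1e-20, qc = 0.99))
  expect_equal(annotate_families(families, h4)$category, "A")
})
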