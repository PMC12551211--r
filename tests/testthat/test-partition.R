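test_that("occupancy reflects exactly the samples whose paths traverse a node", {
  g <- toy_graph()
  p1 <- toy_path("S1", c("s1", "s2", "s3"))
  p2 <- toy_path("S2", c("s1", "a1", "s2", "s3"))
  occ <- compute_occupancy(g, list(p1, p2))
  expect_setequal(node_carriers(occ, "s1"), c("S1", "S2"))
  expect_equal(node_carriers(occ, "a1"), "S2")
  expect_length(node_carriers(occ, "nope"), 0L)

  # generator truth: every alternate-allele node is carried by exactly the
  # planted carriers of that allele
  sim <- small_sim()
  occ2 <- compute_occupancy(sim$emitted$graph, sim$emitted$paths)
  sv <- sim$truth$sv_table
  for (i in seq_len(nrow(sv))) {
    alts <- sim$emitted$sv_nodes[sv_id == sv$sv_id[i], alt_nodes][[1]]
    for (k in seq_along(alts)) {
      planted <- rownames(sim$truth$hap_alleles)[sim$truth$hap_alleles[, i] == k]
      expect_setequal(node_carriers(occ2, alts[k]), planted)
    }
  }
})

test_that("a backbone node skipped by a deletion carrier loses that carrier", {
  g <- toy_graph()
  keeper <- toy_path("S1", c("s1", "s2", "s3"))
  deleter <- toy_path("S2", c("s1", "s3"))
  occ <- compute_occupancy(g, list(keeper, deleter))
  expect_equal(node_carriers(occ, "s2"), "S1")
})

test_that("core/flexible/nested partition is exhaustive, disjoint and conserves bases", {
  g <- toy_graph()
  paths <- list(toy_path("S1", c("s1", "s2", "s3")),
                toy_path("S2", c("s1", "s2", "s3")))
  occ <- compute_occupancy(g, paths)
  part <- partition_core_flexible(occ)
  # all-backbone traversal: backbone core, a1 nested
  expect_equal(part[class == "core", nodes], 3L)
  expect_equal(part[class == "nested", nodes], 1L)
  expect_equal(sum(part$bases), sum(g$nodes$length))

  # 3-node toy: one core, one single-sample flexible, one orphan
  paths2 <- list(toy_path("S1", c("s1", "a1", "s2", "s3")),
                 toy_path("S2", c("s1", "s2", "s3")))
  occ2 <- compute_occupancy(g, paths2)
  part2 <- partition_core_flexible(occ2)
  mem <- attr(part2, "membership")
  expect_setequal(mem$core, c("s1", "s2", "s3"))
  expect_equal(mem$flexible, "a1")

  expect_error(partition_core_flexible(occ, samples = character(0)), "empty")
})

test_that("partition on generator output matches planted node classes", {
  sim <- small_sim()
  occ <- compute_occupancy(sim$emitted$graph, sim$emitted$paths)
  part <- partition_core_flexible(occ)
  mem <- attr(part, "membership")
  nt <- sim$emitted$node_truth
  expect_setequal(mem$nested, nt[class == "nested", node_id])
  expect_true(all(nt[class == "alt", node_id] %in% mem$flexible))
  # conservation identities
  expect_equal(sum(part$bases), sum(sim$emitted$graph$nodes$length))
  covered <- part[class != "nested", sum(bases)]
  expect_equal(covered + part[class == "nested", bases],
               sum(sim$emitted$graph$nodes$length))
})

test_that("per-sample novel contribution credits first carriers and conserves totals", {
  g <- toy_graph()
  ref_like <- toy_path("S1", c("s1", "s2", "s3"))
  carrier_a <- toy_path("S2", c("s1", "a1", "s2", "s3"))
  carrier_b <- toy_path("S3", c("s1", "a1", "s2", "s3"))
  res <- per_sample_novel_contribution(g, list(ref_like, carrier_a, carrier_b),
                                       order = c("S1", "S2", "S3"))
  expect_equal(res$bases, c(0, 60, 0))
  # reversing the order moves the credit but conserves the total
  res2 <- per_sample_novel_contribution(g, list(ref_like, carrier_a, carrier_b),
                                        order = c("S3", "S2", "S1"))
  expect_equal(res2[sample_id == "S3", bases], 60)
  expect_equal(sum(res2$bases), sum(res$bases))

  expect_error(per_sample_novel_contribution(g, list(ref_like), order = "S9"),
               "not in occupancy")

  # property: random permutations of the generator panel conserve the total
  sim <- small_sim()
  base_order <- sim$truth$samples$sample_id
  totals <- vapply(1:3, function(i) {
    set.seed(i)
    sum(per_sample_novel_contribution(sim$emitted$graph, sim$emitted$paths,
                                      order = sample(base_order))$bases)
  }, 0)
  expect_equal(length(unique(totals)), 1L)
})

test_that("NRS extraction applies the three filters with a strict length cut", {
  # backbone-only graph -> empty set
  g0 <- toy_graph()
  occ0 <- compute_occupancy(g0, list(toy_path("S1", c("s1", "s2", "s3"))))
  expect_length(extract_nrs(g0, occ0)$node_ids, 0L)

  # 51 bp carried off-backbone node kept; 50 bp node dropped (strict >)
  nodes <- data.table::data.table(
    node_id = c("s1", "s2", "n51", "n50"),
    sequence = c(strrep("A", 20), strrep("C", 20), strrep("G", 51), strrep("T", 50)),
    length = c(20L, 20L, 51L, 50L), rank = c(0L, 0L, 1L, 1L),
    sn = c("chr1", "chr1", NA, NA), so = c(0L, 20L, NA, NA))
  edges <- data.table::data.table(
    from = c("s1", "s1", "n51", "s1", "n50"), from_orient = "+",
    to = c("s2", "n51", "s2", "n50", "s2"), to_orient = "+")
  g <- pangenome_graph(nodes, edges)
  occ <- compute_occupancy(g, list(toy_path("S1", c("s1", "n51", "s2")),
                                   toy_path("S2", c("s1", "n50", "s2"))))
  nrs <- extract_nrs(g, occ, min_len = 50L)
  expect_equal(nrs$node_ids, "n51")
  expect_equal(nrs$total_bases, 51)
  expect_equal(names(nrs$fasta), "n51")
})

test_that("NRS equals a brute-force triple filter on random graphs", {
  for (s in 1:10) {
    cfg <- sim_config(seed = 1000 + s, n_breeds = 3, samples_per_breed = 2,
                      ref_length = 5e4, n_svs = 8, n_snps = 10, n_nested = 3)
    em <- emit_graph_and_paths(simulate_population(cfg))
    occ <- compute_occupancy(em$graph, em$paths)
    nrs <- extract_nrs(em$graph, occ, min_len = 50L)
    carried <- unique(occ$node_samples$node_id)
    brute <- em$graph$nodes[
      node_id %in% carried & rank > 0L & length > 50L, node_id]
    expect_setequal(nrs$node_ids, brute)
  }
})

test_that("breed-specific features require all carriers in one breed", {
  breed_map <- c(S1 = "HOL", S2 = "HOL", S3 = "NMD", S4 = "NMD", S5 = "HOL")
  lens <- c(f1 = 100, f2 = 200, f3 = 300)
  carriers <- list(f1 = c("S1", "S3"),       # two breeds -> not specific
                   f2 = "S1",                # one of several HOL -> specific
                   f3 = c("S3", "S4"))       # all NMD -> specific
  res <- breed_specific_features(carriers, breed_map, lens)
  expect_equal(res[breed == "HOL", n_features], 1L)
  expect_equal(res[breed == "HOL", bases], 200)
  expect_equal(res[breed == "NMD", bases], 300)
  expect_setequal(attr(res, "features"), c("f2", "f3"))
  expect_error(breed_specific_features(list(f = "S9"), breed_map, c(f = 1)),
               "without breed")

  # brute-force oracle on random carrier sets
  set.seed(9)
  samples <- paste0("S", 1:12)
  bm <- stats::setNames(sample(c("A", "B", "C"), 12, replace = TRUE), samples)
  feats <- lapply(1:40, function(i) sample(samples, sample(1:5, 1)))
  names(feats) <- paste0("f", 1:40)
  fl <- stats::setNames(sample(50:500, 40), names(feats))
  res2 <- breed_specific_features(feats, bm, fl)
  for (b in c("A", "B", "C")) {
    expected <- names(feats)[vapply(feats, function(cr)
      length(unique(bm[cr])) == 1 && unique(bm[cr]) == b, TRUE)]
    expect_equal(res2[breed == b, n_features], length(expected))
    expect_equal(res2[breed == b, bases], sum(fl[expected]))
  }
})
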