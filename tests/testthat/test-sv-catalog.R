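test_that("path projection yields anchors, traversals and deletion evidence", {
  g <- toy_graph()
  # identical to backbone: no deviating segment
  pr <- project_path(toy_path("S1", c("s1", "s2", "s3")), g)
  expect_true(all(!pr$deviates))
  # substitution evidence: s2 skipped, a1 traversed
  pr2 <- project_path(toy_path("S2", c("s1", "a1", "s3")), g)
  dev <- pr2[deviates == TRUE]
  expect_equal(nrow(dev), 1L)
  expect_equal(dev$left_node, "s1")
  expect_equal(dev$right_node, "s3")
  expect_equal(dev$traversal[[1]], "a1")
  # pure deletion: s2 skipped with empty traversal
  pr3 <- project_path(toy_path("S3", c("s1", "s3")), g)
  expect_equal(pr3[deviates == TRUE, traversal][[1]], character(0))
})

test_that("non-collinear backbone visits are dropped and the path flagged", {
  g <- toy_graph()
  p <- sample_path("S1", data.table::data.table(
    chrom = "chr1", node_id = c("s2", "s1", "s3"), orient = "+"))
  expect_message(pr <- project_path(p, g), "non-collinear")
  expect_true(attr(pr, "flagged"))
})

test_that("bubbles are enumerated with deduplicated alleles and correct carriers", {
  g <- toy_graph()
  # nobody deviates -> no bubbles
  bs0 <- enumerate_bubbles(g, list(toy_path("S1", c("s1", "s2", "s3"))))
  expect_length(bs0$bubbles, 0L)

  # two samples share a deletion of s2 -> one bubble, two alleles
  paths <- list(toy_path("S1", c("s1", "s2", "s3")),
                toy_path("S2", c("s1", "s3")),
                toy_path("S3", c("s1", "s3")))
  bs <- enumerate_bubbles(g, paths)
  expect_length(bs$bubbles, 1L)
  b <- bs$bubbles[[1]]
  expect_equal(nrow(b$alleles), 2L)
  expect_equal(b$alleles$len, c(5L, 0L))
  expect_equal(unname(b$carriers[c("S1", "S2", "S3")]), c(0L, 1L, 1L))
  expect_equal(b$ref_start0, 10L)
  expect_equal(b$ref_end0, 15L)
})

test_that("classification follows the biallelic/type rules", {
  mk_bubble <- function(ref_len, alt_lens) {
    seqs <- c(strrep("A", ref_len), vapply(alt_lens, function(l)
      if (l > 0) paste(sample(c("C", "G", "T"), l, replace = TRUE), collapse = "")
      else "", ""))
    list(bubble_id = "b", chrom = "chr1", left_anchor = "x", right_anchor = "y",
         ref_start0 = 10L, ref_end0 = 10L + ref_len,
         alleles = data.table::data.table(
           allele_id = seq_along(seqs) - 1L, seq = seqs, len = nchar(seqs),
           nodes = rep(list(character(0)), length(seqs)),
           is_ref = seq_along(seqs) == 1L),
         carriers = c(S1 = 1L))
  }
  set.seed(1)
  expect_equal(classify_sv(mk_bubble(0, 60))$sv_type, "INS")
  expect_equal(classify_sv(mk_bubble(0, 60))$allelicity, "biallelic")
  expect_equal(classify_sv(mk_bubble(100, 0))$sv_type, "DEL")
  expect_equal(classify_sv(mk_bubble(30, 80))$sv_type, "SUB")
  expect_equal(classify_sv(mk_bubble(0, c(60, 70)))$allelicity, "multiallelic")
  # both sides below the SV threshold: not an SV
  expect_null(classify_sv(mk_bubble(10, 20)))
  # single allele is not a variant site
  one <- mk_bubble(10, integer(0))
  expect_error(classify_sv(one), "single allele")
  # small-allele tolerance reclassifies a 3 bp reference remnant
  expect_equal(classify_sv(mk_bubble(3, 80))$sv_type, "SUB")
  expect_equal(classify_sv(mk_bubble(3, 80), small_allele_tol = 5)$sv_type, "INS")
})

test_that("generator SVs are recovered exactly: site, type, allele and genotype", {
  sim <- small_sim()
  bs <- enumerate_bubbles(sim$emitted$graph, sim$emitted$paths)
  catalog <- classify_sv_catalog(bs)
  m <- match_called_to_planted(catalog, sim$truth)
  expect_equal(m$called$start0, m$planted$start0)
  expect_equal(m$called$end0, m$planted$end0)
  expect_equal(m$called$sv_type, m$planted$sv_type)
  expect_equal(m$called$allelicity, m$planted$allelicity)
  # allele sequences equal the planted alternates (as sets)
  for (i in seq_len(nrow(m$called)))
    expect_setequal(m$called$alt_seqs[[i]],
                    m$planted$alt_seqs[[i]][nzchar(m$planted$alt_seqs[[i]]) |
                                              m$planted$sv_type[i] == "DEL"])
  # genotypes: carriage and, after sequence matching, allele identity
  gt <- catalog$genotypes[rownames(sim$truth$hap_alleles),
                          m$called$sv_id[match(sim$truth$sv_table$sv_id,
                                               m$planted$sv_id)]]
  for (i in seq_len(nrow(m$planted))) {
    planted_gt <- sim$truth$hap_alleles[, m$planted$sv_id[i]]
    called_gt <- catalog$genotypes[names(planted_gt), m$called$sv_id[i]]
    expect_equal(called_gt > 0, planted_gt > 0)
    for (k in seq_along(m$planted$alt_seqs[[i]])) {
      called_k <- match(m$planted$alt_seqs[[i]][k], m$called$alt_seqs[[i]])
      expect_equal(unname(called_gt == called_k), unname(planted_gt == k))
    }
  }
})

test_that("carrier allele sequences equal the planted haplotype substrings", {
  sim <- small_sim()
  bs <- enumerate_bubbles(sim$emitted$graph, sim$emitted$paths)
  catalog <- classify_sv_catalog(bs)
  m <- match_called_to_planted(catalog, sim$truth)
  # every called alternate allele at a site is one of the planted sequences,
  # and the reference allele equals the reference substring
  for (i in seq_len(nrow(m$called))) {
    expect_equal(m$called$ref_seq[i],
                 substr(sim$truth$ref, m$called$start0[i] + 1L, m$called$end0[i]))
  }
})

test_that("NRUI extraction keeps only pure-insertion bubbles above the cut", {
  g <- toy_graph()
  # deletion-only catalogue -> empty NRUI set
  paths <- list(toy_path("S1", c("s1", "s2", "s3")), toy_path("S2", c("s1", "s3")))
  bs <- enumerate_bubbles(g, paths)
  expect_length(extract_nrui(bs, g)$node_ids, 0L)

  # a 60 bp inserted node in a substitution bubble (reference node present)
  # is excluded; in a pure insertion bubble it is kept
  paths2 <- list(toy_path("S1", c("s1", "s2", "s3")),
                 toy_path("S2", c("s1", "a1", "s3")))      # a1 replaces s2: SUB
  bs2 <- enumerate_bubbles(g, paths2)
  expect_length(extract_nrui(bs2, g)$node_ids, 0L)

  paths3 <- list(toy_path("S1", c("s1", "s2", "s3")),
                 toy_path("S2", c("s1", "a1", "s2", "s3")))  # pure INS
  bs3 <- enumerate_bubbles(g, paths3)
  nrui <- extract_nrui(bs3, g)
  expect_equal(nrui$node_ids, "a1")
  expect_equal(nrui$total_bases, 60)
  expect_equal(nrui$carriers$a1, "S2")
})

test_that("NRUI is a subset of NRS on random synthetic graphs", {
  for (s in 1:10) {
    cfg <- sim_config(seed = 2000 + s, n_breeds = 3, samples_per_breed = 2,
                      ref_length = 5e4, n_svs = 10, n_snps = 10)
    em <- emit_graph_and_paths(simulate_population(cfg))
    occ <- compute_occupancy(em$graph, em$paths)
    nrs <- extract_nrs(em$graph, occ, min_len = 50L)
    bs <- enumerate_bubbles(em$graph, em$paths)
    nrui <- extract_nrui(bs, em$graph, min_len = 50L)
    expect_true(all(nrui$node_ids %in% nrs$node_ids))
  }
})

test_that("length spectra conserve counts and show planted modes", {
  pl <- desk_pipeline()
  spec_all <- length_spectrum(pl$catalog)
  expect_equal(sum(spec_all$count), nrow(pl$catalog$svs))
  spec_ins <- length_spectrum(pl$catalog, type = "INS", bin_width = 50L)
  expect_equal(sum(spec_ins$count), sum(pl$catalog$svs$sv_type == "INS"))
  # planted point masses at 150 and 250 bp dominate their bins
  top_bins <- spec_all[order(-count)][1:4, bin_start]
  expect_true(all(c(150L, 250L) %in% top_bins))
  expect_equal(nrow(length_spectrum(classify_sv_catalog(
    structure(list(bubbles = list(), samples = "S1"), class = "bubble_set")))), 0L)
})
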