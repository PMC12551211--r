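test_that("minimal and tag-free GFA files parse with sensible backbones", {
  f <- withr::local_tempfile(fileext = ".gfa")
  writeLines("S\ts1\tACGT", f)
  g <- read_gfa(f)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$backbone$node_id, "s1")

  # explicit backbone for a tag-free two-segment file
  writeLines(c("S\ts1\tACGT", "S\ts2\tGGGG", "L\ts1\t+\ts2\t+\t0M"), f)
  g2 <- read_gfa(f, backbone = c("s1", "s2"))
  expect_equal(g2$backbone$node_id, c("s1", "s2"))
  expect_equal(g2$backbone$start, c(0L, 4L))
})

test_that("malformed or inconsistent GFA input is rejected with line context", {
  f <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("S\ts1\tACGT\tSN:Z:chr1\tSO:i:0\tSR:i:0", "S\ts1"), f)
  expect_error(read_gfa(f), "line 2")
  writeLines(c("S\ts1\tACGT\tSN:Z:chr1\tSO:i:0\tSR:i:0",
               "S\ts1\tACGT\tSN:Z:chr1\tSO:i:4\tSR:i:0"), f)
  expect_error(read_gfa(f), "duplicate")
  writeLines(c("S\ts1\tACGT\tSN:Z:chr1\tSO:i:0\tSR:i:0",
               "S\ts2\tACGT\tSN:Z:chr1\tSO:i:2\tSR:i:0"), f)
  expect_error(read_gfa(f), "overlapping")
})

test_that("graph write/read round trip is the identity, preserving rank tags", {
  g <- toy_graph()
  f <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, f)
  g2 <- read_gfa(f)
  expect_equal(g2$nodes[order(node_id)], g$nodes[order(node_id)])
  setkeyv2 <- function(e) e[order(from, to)]
  expect_equal(setkeyv2(g2$edges), setkeyv2(g$edges))
  expect_equal(g2$backbone, g$backbone)

  # a rank-3 node survives with its tag
  g$nodes[node_id == "a1", rank := 3L]
  write_gfa(g, f)
  expect_true(any(grepl("SR:i:3", readLines(f))))
  expect_equal(read_gfa(f)$nodes[node_id == "a1", rank], 3L)

  # round trip on generator output, including sequence-less emission
  sim <- small_sim()
  write_gfa(sim$emitted$graph, f)
  g3 <- read_gfa(f)
  expect_equal(g3$nodes[order(node_id)], sim$emitted$graph$nodes[order(node_id)])
  expect_equal(nrow(g3$edges), nrow(sim$emitted$graph$edges))
})

test_that("path BED reading validates nodes and edges and round-trips", {
  g <- toy_graph()
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t25\tS1\ts1+,s2+,s3+", f)
  p <- read_path_bed(f, g)
  expect_equal(p$steps$node_id, c("s1", "s2", "s3"))
  expect_equal(p$sample_id, "S1")

  writeLines("chr1\t0\t25\tS1\ts1+,sX+", f)
  expect_error(read_path_bed(f, g), "absent from graph")
  writeLines("chr1\t0\t25\tS1\ts2+,s1+", f)   # no edge s2+ -> s1+
  expect_error(read_path_bed(f, g), "lacking a graph edge")

  writeLines(character(0), f)                 # empty file is a valid empty path
  expect_equal(nrow(read_path_bed(f, g)$steps), 0L)

  p0 <- toy_path("S2", c("s1", "a1", "s2", "s3"))
  write_path_bed(p0, f)
  p1 <- read_path_bed(f, g)
  expect_equal(p1$steps, p0$steps)
  expect_equal(p1$covered, p0$covered)
})

test_that("deletion carriers skip the deleted node in generator paths", {
  sim <- small_sim()
  dels <- sim$truth$sv_table[sv_type == "DEL"]
  expect_gt(nrow(dels), 0)
  i <- which(sim$truth$sv_table$sv_id == dels$sv_id[1])
  carrier <- rownames(sim$truth$hap_alleles)[sim$truth$hap_alleles[, i] > 0][1]
  deleted_nodes <- sim$emitted$sv_nodes[sv_id == dels$sv_id[1], inner][[1]]
  expect_false(any(deleted_nodes %in% sim$emitted$paths[[carrier]]$steps$node_id))
})

test_that("SV VCF writing follows the anchored convention and round-trips genotypes", {
  ref <- c(chr1 = paste0(strrep("A", 100),
                         paste(rep(c("C", "G", "T", "A"), 15), collapse = ""),
                         strrep("T", 100)))
  ins_seq <- paste(rep(c("G", "C"), 30), collapse = "")
  catalog <- list(
    svs = data.table::data.table(
      sv_id = "ins1", chrom = "chr1", start0 = 100L, end0 = 100L,
      sv_type = "INS", allelicity = "biallelic", ref_len = 0L,
      alt_lens = list(60L), ref_seq = "", alt_seqs = list(ins_seq)),
    genotypes = matrix(c(1L, 0L, NA), ncol = 1,
                       dimnames = list(c("X", "Y", "Z"), "ins1")))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(catalog, ref, f)
  rec <- strsplit(grep("^chr1", readLines(f), value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[2]), 100L)
  expect_equal(nchar(rec[5]) - nchar(rec[4]), 60L)
  expect_match(rec[8], "SVTYPE=INS")
  expect_equal(rec[10:12], c("1", "0", "."))

  back <- read_vcf(f)
  expect_equal(back$genotypes, catalog$genotypes)
  expect_equal(back$svs$alt_seqs[[1]], ins_seq)

  # disagreeing REF is refused
  bad <- catalog
  bad$svs$ref_seq <- "TTTT"
  bad$svs$end0 <- 104L
  expect_error(write_vcf(bad, ref, f), "disagrees with reference")
})

test_that("a multiallelic bubble becomes one record with comma-separated ALTs", {
  ref <- c(chr1 = strrep("ACGT", 50))
  catalog <- list(
    svs = data.table::data.table(
      sv_id = "m1", chrom = "chr1", start0 = 20L, end0 = 20L,
      sv_type = "INS", allelicity = "multiallelic", ref_len = 0L,
      alt_lens = list(c(60L, 70L, 80L)), ref_seq = "",
      alt_seqs = list(c(strrep("A", 60), strrep("C", 70), strrep("G", 80)))),
    genotypes = matrix(c(0L, 1L, 2L, 3L), ncol = 1,
                       dimnames = list(paste0("S", 1:4), "m1")))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(catalog, ref, f)
  rec <- strsplit(grep("^chr1", readLines(f), value = TRUE), "\t")[[1]]
  expect_length(strsplit(rec[5], ",")[[1]], 3L)
  back <- read_vcf(f)
  expect_equal(unname(back$genotypes[, 1]), 0:3)
})

test_that("full VCF round trip preserves the generator's genotype matrix", {
  pl <- desk_pipeline()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pl$catalog, stats::setNames(pl$truth$ref, pl$truth$chrom), f)
  back <- read_vcf(f)
  expect_identical(back$genotypes, pl$catalog$genotypes)
  expect_equal(back$svs$sv_type, pl$catalog$svs$sv_type)

  # independent parser agrees on positions and genotype calls
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), pl$catalog$svs$start0)
  gt <- t(vcfR::extract.gt(v, element = "GT"))
  gt_int <- suppressWarnings(matrix(as.integer(gt), nrow(gt),
                                    dimnames = dimnames(gt)))
  expect_equal(gt_int[rownames(pl$catalog$genotypes), ],
               pl$catalog$genotypes, ignore_attr = TRUE)
})

test_that("genotype/phenotype/metadata tables load consistently", {
  gf <- withr::local_tempfile(fileext = ".tsv")
  pf <- withr::local_tempfile(fileext = ".tsv")
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tchrom\tpos\tS1\tS2\tS3",
               "m1\tchr1\t100\t0\t1\t2",
               "m2\tchr1\t200\t2\tNA\t0"), gf)
  writeLines(c("animal\ttrait\tdyd\tweight",
               "S1\tHS\t0.5\t30", "S2\tHS\t-0.2\t50", "S9\tHS\t1.0\t10"), pf)
  writeLines(c("sample\tbreed", "S1\tHOL", "S2\tNMD", "S3\tHOL"), mf)
  expect_warning(tabs <- read_tables(gf, pf, mf), "S9")
  expect_equal(dim(tabs$dosages), c(3L, 2L))
  expect_equal(unname(tabs$dosages["S2", ]), c(1, NA))
  expect_false("S9" %in% tabs$phenotypes$animal)
  expect_equal(unname(tabs$breeds["S2"]), "NMD")

  # VCF genotypes: GT 0/1 is dosage 1
  vf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
               "chr1\t10\tv1\tA\tT\t.\tPASS\t.\tGT\t0/1\t1/1",
               "chr1\t20\tv2\tA\tT\t.\tPASS\t.\tGT\t./.\t0/0"), vf)
  tv <- read_tables(vf)
  expect_equal(unname(tv$dosages["S1", ]), c(1, NA))
  expect_equal(unname(tv$dosages["S2", ]), c(2, 0))
})
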