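# Shared fixtures: a hand-built toy graph and memoised simulation runs so
# expensive objects are built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Three backbone segments with one 60 bp insertion allele between s1 and s2
# and a deletion skip over s2.
toy_graph <- function() {
  nodes <- data.table::data.table(
    node_id = c("s1", "s2", "s3", "a1"),
    sequence = c(strrep("A", 10), strrep("C", 5), strrep("G", 10),
                 paste(rep(c("T", "G"), 30), collapse = "")),
    length = c(10L, 5L, 10L, 60L),
    rank = c(0L, 0L, 0L, 1L),
    sn = c("chr1", "chr1", "chr1", NA),
    so = c(0L, 10L, 15L, NA))
  edges <- data.table::data.table(
    from = c("s1", "s2", "s1", "a1", "s1"),
    from_orient = "+",
    to = c("s2", "s3", "a1", "s2", "s3"),
    to_orient = "+")
  pangenome_graph(nodes, edges)
}

toy_path <- function(sample_id, node_ids, breed = NA_character_) {
  sample_path(sample_id,
              data.table::data.table(chrom = "chr1", node_id = node_ids,
                                     orient = "+"),
              covered = data.table::data.table(chrom = "chr1", start = 0L,
                                               end = 25L),
              breed = breed)
}

# Small simulated population reused by graph/partition/catalog tests.
small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(seed = 42, n_breeds = 4, samples_per_breed = 3,
                      ref_length = 2e5, n_svs = 30, n_snps = 100)
    truth <- simulate_population(cfg)
    list(cfg = cfg, truth = truth, emitted = emit_graph_and_paths(truth))
  })
}

# The desk-preset end-to-end pipeline (also used by the acceptance tests).
desk_pipeline <- function() {
  cached("desk_pipeline",
         run_pipeline(sim_config(seed = 11),
                      io_dir = file.path(tempdir(), "desk_pipeline")))
}

# Map called alleles onto planted alleles by alternate-sequence identity,
# so multiallelic sites compare correctly whatever the discovery order.
match_called_to_planted <- function(catalog, truth) {
  called <- catalog$svs[order(catalog$svs$start0)]
  planted <- truth$sv_table[order(truth$sv_table$start0)]
  stopifnot(nrow(called) == nrow(planted))
  list(called = called, planted = planted)
}
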