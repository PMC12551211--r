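# End-to-end desk-scale pipeline: simulate a population, emit and re-read
# the graph and paths, partition, call and classify SVs, convert deletions
# to virtual SNPs, cluster the PAV matrix, and run the weighted
# mixed-model association scan with QTL grouping on a diploid cohort.

#' Run the full pipeline on a simulated population
#'
#' Drives every stage of the package against one simulated multi-breed
#' population: graph/path emission (with a file round trip when `io_dir`
#' is given), node occupancy and core/flexible/nested partition, NRS
#' extraction, bubble enumeration, SV classification and genotyping, NRUI
#' extraction, deletion-to-virtual-SNP conversion, PAV hierarchical
#' clustering against the breed labels, and a GWAS on a diploid cohort with
#' a planted causal deletion, ending in LD-window QTL regions.
#'
#' @param cfg A [sim_config]; its seed drives all randomness.
#' @param n_cohort_per_breed Diploid animals per breed for the GWAS cohort
#'   (default 60, giving n = 840 under the desk preset, the scale at which a
#'   5%-variance effect is reliably detectable).
#' @param io_dir Optional directory: graph, paths, reference, VCF and
#'   tables are written there and the graph and paths re-read from disk
#'   before analysis (exercising the parsers end to end).
#' @return A list with the intermediate objects of every stage (`truth`,
#'   `graph`, `paths`, `partition`, `nrs`, `bubbles`, `catalog`, `nrui`,
#'   `vsnp`, `clustering` with `ari`, `cohort`, `null_fit`, `scan`,
#'   `threshold`, `qtl`, `causal` bookkeeping).
#' @export
run_pipeline <- function(cfg = sim_config(), n_cohort_per_breed = 60L,
                         io_dir = NULL) {
  truth <- simulate_population(cfg)
  emitted <- emit_graph_and_paths(truth, dir = io_dir)
  graph <- emitted$graph
  paths <- emitted$paths
  if (!is.null(io_dir)) {
    graph <- read_gfa(emitted$files$gfa)
    breed_map <- setNames(truth$samples$breed, truth$samples$sample_id)
    paths <- lapply(list.files(emitted$files$paths_dir, full.names = TRUE),
                    function(f) {
                      p <- read_path_bed(f, graph)
                      p$breed <- breed_map[[p$sample_id]]
                      p
                    })
    names(paths) <- vapply(paths, function(p) p$sample_id, "")
    paths <- paths[truth$samples$sample_id]
  }

  occ <- compute_occupancy(graph, paths)
  partition <- partition_core_flexible(occ)
  novel <- per_sample_novel_contribution(graph, paths,
                                         order = truth$samples$sample_id)
  nrs <- extract_nrs(graph, occ, min_len = 50L)

  bubbles <- enumerate_bubbles(graph, paths)
  catalog <- classify_sv_catalog(bubbles)
  nrui <- extract_nrui(bubbles, graph, min_len = 50L)
  reference <- setNames(truth$ref, truth$chrom)
  if (!is.null(io_dir))
    write_vcf(catalog, reference, file.path(io_dir, "svs.vcf"))
  vsnp <- convert_deletions(catalog, reference)

  carriers <- lapply(seq_len(ncol(catalog$genotypes)), function(j) {
    g <- catalog$genotypes[, j]
    names(g)[!is.na(g) & g > 0L]
  })
  names(carriers) <- colnames(catalog$genotypes)
  pav <- build_pav(carriers, truth$samples$sample_id)
  cl <- hcluster_pav(pav, k = cfg$n_breeds)
  breed_of <- setNames(truth$samples$breed, truth$samples$sample_id)
  ari <- adjusted_rand_index(cl$labels, breed_of[names(cl$labels)])

  cohort <- simulate_cohort(truth, n_per_breed = n_cohort_per_breed,
                            seed = cfg$seed + 100L)
  G <- compute_grm(cohort$snp_dosages)
  rownames(G) <- colnames(G) <- cohort$samples$animal

  dels <- truth$sv_table[sv_type == "DEL", sv_id]
  maf <- colMeans(cohort$sv_dosages[, dels, drop = FALSE]) / 2
  maf <- pmin(maf, 1 - maf)
  causal_id <- dels[which.max(maf)]
  set.seed(cfg$seed + 200L)
  weights <- runif(nrow(G), cfg$weight_range[1], cfg$weight_range[2])
  sim_ph <- simulate_phenotypes(G, h2 = cfg$h2,
                                causal_dosage = cohort$sv_dosages[, causal_id],
                                causal_var_frac = cfg$causal_var_frac,
                                weights = weights, seed = cfg$seed + 300L)
  y <- sim_ph$phenotypes$dyd

  null_fit <- fit_null_reml(y, G, weights = weights)
  X <- cbind(cohort$sv_dosages, cohort$snp_dosages)
  scan <- mlma_scan(y, X, null = null_fit)
  scan <- cohort$markers[scan, on = "marker_id"]
  thr <- bonferroni(0.05, ncol(X))
  qtl <- group_qtl(scan, X, threshold_neglogp = thr$neg_log10)

  causal_region <- NA_integer_; causal_top_sv <- FALSE
  if (nrow(qtl)) {
    hit <- which(vapply(qtl$members, function(m) causal_id %in% m, TRUE))
    if (length(hit)) {
      causal_region <- qtl$region[hit[1L]]
      mem <- scan[marker_id %in% qtl$members[[hit[1L]]] & panel == "SV"]
      causal_top_sv <- nrow(mem) > 0 &&
        mem$marker_id[which.max(mem$neg_log10_p)] == causal_id
    }
  }

  list(truth = truth, graph = graph, paths = paths, occupancy = occ,
       partition = partition, novel = novel, nrs = nrs, bubbles = bubbles,
       catalog = catalog, nrui = nrui, vsnp = vsnp,
       clustering = list(result = cl, ari = ari, pav = pav),
       cohort = cohort, G = G, phenotype_sim = sim_ph, null_fit = null_fit,
       scan = scan, threshold = thr, qtl = qtl,
       causal = list(sv_id = causal_id, region = causal_region,
                     top_sv_in_region = causal_top_sv,
                     beta_true = sim_ph$truth$beta,
                     beta_hat = scan[marker_id == causal_id, beta]))
}

utils::globalVariables(c("panel", "beta", "sv_id"))
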