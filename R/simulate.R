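# Deterministic simulator of a multi-breed, cattle-like assembly panel with
# planted structural variants, the matching reference-backbone graph and
# per-sample paths, plus diploid genotype cohorts and mixed-model phenotypes.
# Every stage of the pipeline is testable against the ground truth returned
# here.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic population: a single
#' reference chromosome, a fixed number of breeds with a small number of
#' assemblies each, planted structural variants (insertions, deletions,
#' substitutions, a fraction multiallelic) with a transposable-element-like
#' length mixture, SNP markers with breed-divergent allele frequencies, and
#' mixed-model phenotype parameters.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_breeds Number of breeds.
#' @param samples_per_breed Assemblies per breed (scalar or length-`n_breeds`
#'   vector; the desk preset uses 4 per breed).
#' @param ref_length Reference chromosome length in bp.
#' @param n_svs Number of planted SVs (non-overlapping on the reference).
#' @param sv_type_mix Named probabilities for `INS`, `DEL`, `SUB`.
#' @param multiallelic_frac Fraction of INS/SUB sites given two alternate
#'   alleles (deletions are kept biallelic).
#' @param sv_len_modes,sv_len_mode_probs Point masses of the SV length
#'   mixture (bp) and their probabilities; the remainder of the mass is a
#'   log-normal body (`meanlog = log(300)`, `sdlog = 1`) truncated to
#'   `[min_sv_len, max_sv_len]`. Defaults put modes at 150, 250 and 5,500 bp,
#'   the repeat-family peaks seen in real cattle SV length spectra.
#' @param min_sv_len,max_sv_len Bounds on planted allele lengths (bp).
#' @param divergence Fst-like breed-divergence parameter of the
#'   Balding-Nichols per-breed allele-frequency draw.
#' @param breed_private_frac Fraction of SVs segregating in a single breed.
#' @param n_nested Decoy nodes wired into the graph but traversed by no
#'   sample path (the "nested node" artefact of graph realignment).
#' @param n_snps SNP markers simulated for relationship/GWAS use.
#' @param h2 Narrow-sense heritability of the simulated trait.
#' @param causal_var_frac Phenotypic variance fraction explained by the
#'   planted causal SV.
#' @param weight_range Range of per-animal accuracy weights (e.g. effective
#'   daughter counts); residual variance for animal i is `sigma_e^2 / w_i`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_breeds = 14L,
                       samples_per_breed = 4L,
                       ref_length = 2e6,
                       n_svs = 120L,
                       sv_type_mix = c(INS = 0.4, DEL = 0.4, SUB = 0.2),
                       multiallelic_frac = 0.1,
                       sv_len_modes = c(150L, 250L, 5500L),
                       sv_len_mode_probs = c(0.20, 0.15, 0.05),
                       min_sv_len = 50L,
                       max_sv_len = 10000L,
                       divergence = 0.15,
                       breed_private_frac = 0.2,
                       n_nested = 5L,
                       n_snps = 2000L,
                       h2 = 0.5,
                       causal_var_frac = 0.05,
                       weight_range = c(20, 200)) {
  stopifnot(n_breeds >= 1, all(samples_per_breed >= 1), ref_length >= 1e4,
            n_svs >= 0, abs(sum(sv_type_mix) - 1) < 1e-8,
            multiallelic_frac >= 0, multiallelic_frac <= 1,
            sum(sv_len_mode_probs) <= 1, divergence > 0, divergence < 1,
            breed_private_frac >= 0, breed_private_frac <= 1,
            h2 >= 0, h2 <= 1, causal_var_frac >= 0)
  if (length(samples_per_breed) == 1L)
    samples_per_breed <- rep(samples_per_breed, n_breeds)
  stopifnot(length(samples_per_breed) == n_breeds)
  cfg <- list(seed = as.integer(seed), n_breeds = as.integer(n_breeds),
              samples_per_breed = as.integer(samples_per_breed),
              ref_length = as.integer(ref_length), n_svs = as.integer(n_svs),
              sv_type_mix = sv_type_mix, multiallelic_frac = multiallelic_frac,
              sv_len_modes = sv_len_modes, sv_len_mode_probs = sv_len_mode_probs,
              min_sv_len = as.integer(min_sv_len), max_sv_len = as.integer(max_sv_len),
              divergence = divergence, breed_private_frac = breed_private_frac,
              n_nested = as.integer(n_nested), n_snps = as.integer(n_snps),
              h2 = h2, causal_var_frac = causal_var_frac,
              weight_range = weight_range)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a reference chromosome sequence
#'
#' @param length Sequence length in bp (>= 10 kb).
#' @param seed Integer seed.
#' @return Uppercase ACGT character string, deterministic for a seed.
#' @export
simulate_reference <- function(length, seed = 1L) {
  stopifnot(length >= 1e4)
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

.random_dna <- function(n) {
  vapply(n, function(k) paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                              collapse = ""), "")
}

.draw_sv_lengths <- function(n, cfg) {
  comp <- sample.int(length(cfg$sv_len_modes) + 1L, n, replace = TRUE,
                     prob = c(cfg$sv_len_mode_probs, 1 - sum(cfg$sv_len_mode_probs)))
  len <- integer(n)
  body <- comp > length(cfg$sv_len_modes)
  len[!body] <- cfg$sv_len_modes[comp[!body]]
  if (any(body)) {
    draw <- round(rlnorm(sum(body), meanlog = log(300), sdlog = 1))
    len[body] <- pmin(pmax(draw, cfg$min_sv_len), cfg$max_sv_len)
  }
  as.integer(len)
}

.balding_nichols <- function(p0, n_breeds, fst) {
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  pmin(pmax(rbeta(n_breeds, a, b), 0), 1)
}

#' Simulate a multi-breed assembly population with planted variants
#'
#' Plants non-overlapping SVs on a simulated reference, draws per-breed
#' alternate-allele frequencies (Balding-Nichols spread controlled by
#' `divergence`, with a configurable fraction of breed-private sites),
#' assigns each haploid assembly an allele at every site, and builds each
#' sample's haplotype by editing the reference. SNP markers with
#' breed-divergent frequencies are drawn alongside. Every planted SV is
#' guaranteed at least one alternate carrier in the panel so that each site
#' is discoverable from the emitted paths, and alternate alleles no
#' assembly carries are pruned (a graph built from assemblies contains only
#' sequence some assembly contributed), so the recorded allelicity is the
#' realized one.
#'
#' @param cfg A [sim_config].
#' @return A `sim_truth` list: `cfg`, `chrom`, `ref` (character), `samples`
#'   (`data.table` of `sample_id`, `breed`), `sv_table` (planted sites with
#'   types, intervals, alternate sequences and per-breed frequencies),
#'   `hap_alleles` (samples x SVs matrix of allele indices, 0 = reference),
#'   `snps` (positions and per-breed frequencies) and `haplotypes` (named
#'   character vector of edited sequences).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom <- "chr1"
  ref <- paste(sample(c("A", "C", "G", "T"), cfg$ref_length, replace = TRUE),
               collapse = "")

  breeds <- sprintf("B%02d", seq_len(cfg$n_breeds))
  samples <- rbindlist(lapply(seq_len(cfg$n_breeds), function(b)
    data.table(sample_id = sprintf("%s_S%d", breeds[b],
                                   seq_len(cfg$samples_per_breed[b])),
               breed = breeds[b])))

  n <- cfg$n_svs
  types <- sample(names(cfg$sv_type_mix), n, replace = TRUE, prob = cfg$sv_type_mix)
  ref_lens <- ifelse(types == "INS", 0L, .draw_sv_lengths(n, cfg))
  n_alts <- ifelse(types != "DEL" & runif(n) < cfg$multiallelic_frac, 2L, 1L)
  alt_lens <- lapply(seq_len(n), function(i) {
    if (types[i] == "DEL") 0L else .draw_sv_lengths(n_alts[i], cfg)
  })

  # place the reference footprints left to right with a minimum gap
  margin <- 500L; gap <- 200L
  free <- cfg$ref_length - 2L * margin - sum(ref_lens) - (n + 1L) * gap
  if (free <= 0) stop("requested SVs do not fit on the reference without overlap")
  cuts <- sort(runif(n, 0, free))
  extra <- diff(c(0, cuts))
  starts <- integer(n); at <- margin
  for (i in seq_len(n)) {
    at <- at + gap + as.integer(round(extra[i]))
    starts[i] <- at
    at <- at + ref_lens[i]
  }
  ends <- starts + ref_lens                      # 0-based half-open

  private_breed <- ifelse(runif(n) < cfg$breed_private_frac,
                          sample(breeds, n, replace = TRUE), NA_character_)
  freqs <- lapply(seq_len(n), function(i) {
    k <- n_alts[i]
    if (!is.na(private_breed[i])) {
      f <- matrix(0, nrow = cfg$n_breeds, ncol = k,
                  dimnames = list(breeds, NULL))
      tot <- runif(1, 0.25, 0.75)
      f[private_breed[i], ] <- if (k == 1L) tot else
        tot * c(u <- runif(1, 0.3, 0.7), 1 - u)
      f
    } else {
      p0 <- runif(1, 0.1, 0.6)
      tot <- .balding_nichols(p0, cfg$n_breeds, cfg$divergence)
      if (k == 1L) matrix(tot, ncol = 1, dimnames = list(breeds, NULL)) else {
        u <- runif(1, 0.3, 0.7)
        matrix(c(tot * u, tot * (1 - u)), ncol = 2,
               dimnames = list(breeds, NULL))
      }
    }
  })

  # haploid allele per sample per SV; redraw sites left with no alt carrier
  n_samp <- nrow(samples)
  hap <- matrix(0L, nrow = n_samp, ncol = n,
                dimnames = list(samples$sample_id, sprintf("sv%03d", seq_len(n))))
  for (i in seq_len(n)) {
    f <- freqs[[i]]
    repeat {
      draw <- vapply(seq_len(n_samp), function(s) {
        fb <- f[samples$breed[s], ]
        sample.int(length(fb) + 1L, 1L, prob = c(1 - sum(fb), fb)) - 1L
      }, 0L)
      if (any(draw > 0L)) break
    }
    hap[, i] <- draw
  }

  # an allele no assembly carries contributes no sequence to the graph:
  # drop uncarried alternates and renumber, so multiallelic sites where a
  # second alternate failed to segregate become biallelic
  for (i in seq_len(n)) {
    carried <- sort(unique(hap[hap[, i] > 0L, i]))
    if (length(carried) < n_alts[i]) {
      hap[, i] <- ifelse(hap[, i] == 0L, 0L,
                         as.integer(match(hap[, i], carried)))
      alt_lens[[i]] <- alt_lens[[i]][carried]
      freqs[[i]] <- freqs[[i]][, carried, drop = FALSE]
      n_alts[i] <- length(carried)
    }
  }

  alt_seqs <- lapply(seq_len(n), function(i) {
    if (types[i] == "DEL") "" else .random_dna(alt_lens[[i]])
  })

  sv_table <- data.table(
    sv_id = colnames(hap), chrom = chrom, sv_type = types,
    start0 = starts, end0 = ends, ref_len = ref_lens,
    n_alts = n_alts, alt_seqs = alt_seqs,
    alt_lens = lapply(alt_seqs, nchar),
    allelicity = ifelse(n_alts > 1L, "multiallelic", "biallelic"),
    private_breed = private_breed, freqs = freqs)

  haplotypes <- setNames(vapply(seq_len(n_samp), function(s) {
    pieces <- character(0)
    at <- 1L                                     # 1-based cursor on ref
    for (i in seq_len(n)) {
      a <- hap[s, i]
      pieces <- c(pieces, substr(ref, at, starts[i]))   # up to the site
      pieces <- c(pieces,
                  if (a == 0L) substr(ref, starts[i] + 1L, ends[i])
                  else alt_seqs[[i]][a])
      at <- ends[i] + 1L
    }
    paste(c(pieces, substr(ref, at, cfg$ref_length)), collapse = "")
  }, ""), samples$sample_id)

  snp_pos <- sort(sample.int(cfg$ref_length, cfg$n_snps))
  snp_p0 <- runif(cfg$n_snps, 0.05, 0.95)
  snp_freq <- t(vapply(snp_p0, .balding_nichols, numeric(cfg$n_breeds),
                       n_breeds = cfg$n_breeds, fst = cfg$divergence))
  colnames(snp_freq) <- breeds
  snps <- data.table(marker_id = sprintf("snp%05d", seq_len(cfg$n_snps)),
                     chrom = chrom, pos = snp_pos, p0 = snp_p0)

  truth <- list(cfg = cfg, chrom = chrom, ref = ref, breeds = breeds,
                samples = samples, sv_table = sv_table, hap_alleles = hap,
                snps = snps, snp_freq = snp_freq, haplotypes = haplotypes)
  class(truth) <- "sim_truth"
  truth
}

#' Emit the pangenome graph and per-sample paths for a simulated population
#'
#' Builds the reference backbone by splitting the reference at every SV
#' breakpoint (rank-0 nodes with origin tags), adds one off-backbone node
#' per alternate allele (rank = order of the earliest carrier), wires the
#' edges realising every allele traversal (including deletion skip edges),
#' and derives each sample's path so that concatenating the path's node
#' sequences spells the sample's haplotype exactly. Optionally writes
#' `graph.gfa`, `paths/*.bed`, `ref.fa` and `breeds.tsv` to a directory.
#'
#' @param truth A `sim_truth` from [simulate_population].
#' @param dir Optional output directory.
#' @return List with `graph` ([pangenome_graph]), `paths` (list of
#'   [sample_path]), `node_truth` (`data.table` of every node's planted
#'   class: `backbone`, `alt` or `nested`, with owning SV), `sv_nodes`
#'   (anchor and allele node bookkeeping per SV) and, if `dir` is given,
#'   `files`.
#' @export
emit_graph_and_paths <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$cfg
  sv <- truth$sv_table
  chrom <- truth$chrom
  set.seed(cfg$seed + 1L)                         # nested decoys only

  bp <- sort(unique(c(0L, sv$start0, sv$end0, cfg$ref_length)))
  seg <- data.table(start = bp[-length(bp)], end = bp[-1L])
  seg <- seg[end > start]
  seg[, node_id := sprintf("s%04d", .I)]
  seg[, sequence := substring(truth$ref, start + 1L, end)]

  seg_at_start <- setNames(seg$node_id, seg$start)  # segment starting at x
  seg_before <- setNames(seg$node_id, seg$end)      # segment ending at x

  # introduction rank: earliest carrier's position in the sample order
  intro_rank <- apply(truth$hap_alleles, 2, function(a) {
    hit <- which(a > 0L)
    if (length(hit)) hit[1L] else 1L
  })

  alt_rows <- list(); sv_nodes <- list(); extra_edges <- list()
  for (i in seq_len(nrow(sv))) {
    left <- seg_before[[as.character(sv$start0[i])]]
    right <- seg_at_start[[as.character(sv$end0[i])]]
    inner <- if (sv$end0[i] > sv$start0[i])
      seg[start >= sv$start0[i] & end <= sv$end0[i], node_id] else character(0)
    alts <- character(0)
    for (k in seq_len(sv$n_alts[i])) {
      aseq <- sv$alt_seqs[[i]][k]
      if (nzchar(aseq)) {
        nid <- sprintf("%s_a%d", sv$sv_id[i], k)
        alts <- c(alts, nid)
        alt_rows[[length(alt_rows) + 1L]] <- data.table(
          node_id = nid, sequence = aseq, length = nchar(aseq),
          rank = as.integer(intro_rank[i]), sn = NA_character_, so = NA_integer_)
        extra_edges[[length(extra_edges) + 1L]] <- data.table(
          from = c(left, nid), from_orient = "+",
          to = c(nid, right), to_orient = "+")
      } else {                                    # deletion: skip edge
        extra_edges[[length(extra_edges) + 1L]] <- data.table(
          from = left, from_orient = "+", to = right, to_orient = "+")
      }
    }
    sv_nodes[[i]] <- data.table(sv_id = sv$sv_id[i], left_anchor = left,
                                right_anchor = right, inner = list(inner),
                                alt_nodes = list(alts))
  }
  sv_nodes <- rbindlist(sv_nodes)

  nested_rows <- NULL
  if (cfg$n_nested > 0L) {
    host <- sample(nrow(seg) - 1L, cfg$n_nested, replace = TRUE)
    nested_rows <- data.table(
      node_id = sprintf("nested%02d", seq_len(cfg$n_nested)),
      sequence = .random_dna(sample(100:1000, cfg$n_nested, replace = TRUE)),
      rank = max(1L, max(c(1L, intro_rank))), sn = NA_character_, so = NA_integer_)
    nested_rows[, length := nchar(sequence)]
    extra_edges[[length(extra_edges) + 1L]] <- data.table(
      from = c(seg$node_id[host], nested_rows$node_id), from_orient = "+",
      to = c(nested_rows$node_id, seg$node_id[host + 1L]), to_orient = "+")
  }

  nodes <- rbindlist(list(
    data.table(node_id = seg$node_id, sequence = seg$sequence,
               length = nchar(seg$sequence), rank = 0L, sn = chrom, so = seg$start),
    if (length(alt_rows)) rbindlist(alt_rows),
    nested_rows), use.names = TRUE, fill = TRUE)

  backbone_edges <- data.table(
    from = seg$node_id[-nrow(seg)], from_orient = "+",
    to = seg$node_id[-1L], to_orient = "+")
  edges <- unique(rbindlist(c(list(backbone_edges), extra_edges)))
  graph <- pangenome_graph(nodes, edges)

  # per-sample walks: backbone segments keyed by start, SV alleles overriding
  seg_keys <- as.numeric(seg$start)
  inner_of <- lapply(seq_len(nrow(sv)), function(i) sv_nodes$inner[[i]])
  paths <- lapply(seq_len(nrow(truth$samples)), function(s) {
    keep <- setNames(rep(TRUE, nrow(seg)), seg$node_id)
    ins <- list()
    for (i in seq_len(nrow(sv))) {
      a <- truth$hap_alleles[s, i]
      if (a == 0L) next
      keep[inner_of[[i]]] <- FALSE
      aseq <- sv$alt_seqs[[i]][a]
      if (nzchar(aseq))
        ins[[length(ins) + 1L]] <- data.table(
          ord = sv$start0[i] - 0.5, node_id = sprintf("%s_a%d", sv$sv_id[i], a))
    }
    walk <- data.table(ord = seg_keys[keep[seg$node_id]],
                       node_id = seg$node_id[keep[seg$node_id]])
    if (length(ins)) walk <- rbindlist(c(list(walk), ins))
    setorder(walk, ord)
    sample_path(truth$samples$sample_id[s],
                data.table(chrom = chrom, node_id = walk$node_id, orient = "+"),
                covered = data.table(chrom = chrom, start = 0L,
                                     end = cfg$ref_length),
                breed = truth$samples$breed[s])
  })
  names(paths) <- truth$samples$sample_id

  node_truth <- nodes[, .(node_id,
                          class = ifelse(rank == 0L, "backbone",
                                  ifelse(startsWith(node_id, "nested"), "nested",
                                         "alt")))]

  out <- list(graph = graph, paths = paths, node_truth = node_truth,
              sv_nodes = sv_nodes)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "paths"), recursive = TRUE, showWarnings = FALSE)
    write_gfa(graph, file.path(dir, "graph.gfa"))
    for (p in paths) write_path_bed(p, file.path(dir, "paths",
                                                 paste0(p$sample_id, ".bed")))
    ref_set <- Biostrings::DNAStringSet(setNames(truth$ref, chrom))
    Biostrings::writeXStringSet(ref_set, file.path(dir, "ref.fa"))
    fwrite(truth$samples[, .(sample = sample_id, breed)],
           file.path(dir, "breeds.tsv"), sep = "\t")
    out$files <- list(gfa = file.path(dir, "graph.gfa"),
                      paths_dir = file.path(dir, "paths"),
                      ref = file.path(dir, "ref.fa"),
                      breeds = file.path(dir, "breeds.tsv"))
  }
  out
}

#' Simulate a diploid genotyped cohort from the planted allele frequencies
#'
#' Draws Hardy-Weinberg genotypes within breed for the planted SVs
#' (multiallelic sites collapse to carriage of any alternate allele) and the
#' simulated SNP panel. Used for marker-statistics, PCA and GWAS stages,
#' which operate on genotyped populations much larger than the assembly
#' panel.
#'
#' @param truth A `sim_truth`.
#' @param n_per_breed Diploid animals per breed (scalar or vector).
#' @param seed Seed for the cohort draw.
#' @param breeds Optional subset of breed labels to include.
#' @return List with `samples` (`data.table`: `animal`, `breed`),
#'   `sv_dosages` and `snp_dosages` (animals x markers, 0/1/2) and `markers`
#'   (`data.table` of ids and positions for both panels).
#' @export
simulate_cohort <- function(truth, n_per_breed = 50L, seed = 1L, breeds = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  breeds <- breeds %||% truth$breeds
  if (length(n_per_breed) == 1L) n_per_breed <- rep(n_per_breed, length(breeds))
  samples <- rbindlist(lapply(seq_along(breeds), function(b)
    data.table(animal = sprintf("%s_A%04d", breeds[b], seq_len(n_per_breed[b])),
               breed = breeds[b])))
  n <- nrow(samples)
  sv_freq <- vapply(truth$sv_table$freqs, function(f)
    rowSums(f)[breeds], numeric(length(breeds)))   # any-alt frequency per breed
  if (is.null(dim(sv_freq))) sv_freq <- matrix(sv_freq, nrow = length(breeds))
  draw_panel <- function(freq_by_breed, ids) {
    m <- ncol(freq_by_breed)
    out <- matrix(0L, nrow = n, ncol = m, dimnames = list(samples$animal, ids))
    for (b in seq_along(breeds)) {
      rows <- which(samples$breed == breeds[b])
      out[rows, ] <- matrix(rbinom(length(rows) * m, 2L,
                                   rep(freq_by_breed[b, ], each = length(rows))),
                            nrow = length(rows))
    }
    out
  }
  rownames(sv_freq) <- breeds
  sv_dos <- draw_panel(sv_freq, truth$sv_table$sv_id)
  snp_dos <- draw_panel(t(truth$snp_freq[, breeds, drop = FALSE]),
                        truth$snps$marker_id)
  markers <- rbindlist(list(
    truth$sv_table[, .(marker_id = sv_id, chrom, pos = start0, panel = "SV")],
    truth$snps[, .(marker_id, chrom, pos, panel = "SNP")]))
  list(samples = samples, sv_dosages = sv_dos, snp_dosages = snp_dos,
       markers = markers)
}

#' Simulate phenotypes under the weighted mixed linear model
#'
#' Generates daughter-yield-deviation-like records `y = mu + x beta + u + e`
#' with polygenic effects `u ~ N(0, G sigma_u^2)` and heteroscedastic
#' residuals `e_i ~ N(0, sigma_e^2 / w_i)` for per-animal accuracy weights
#' `w_i`. Variances are scaled so the expected phenotypic variance is 1:
#' `sigma_u^2 = h2` and `sigma_e^2 = (1 - h2) / mean(1/w)`. The causal
#' effect size is chosen so the causal marker explains `causal_var_frac` of
#' the phenotypic variance.
#'
#' @param G Genomic relationship matrix (n x n, PSD).
#' @param h2 Heritability.
#' @param causal_dosage Optional dosage vector of the causal marker.
#' @param causal_var_frac Variance fraction explained by the causal marker.
#' @param weights Per-animal accuracy weights `w_i`; default all 1.
#' @param mu Overall mean.
#' @param seed Seed.
#' @param trait Trait label written into the phenotype table.
#' @return List with `phenotypes` (`data.table`: `animal`, `trait`, `dyd`,
#'   `weight`) and `truth` (`beta`, `sigma_u2`, `sigma_e2`).
#' @export
simulate_phenotypes <- function(G, h2 = 0.5, causal_dosage = NULL,
                                causal_var_frac = 0.05, weights = NULL,
                                mu = 0, seed = 1L, trait = "TRAIT") {
  n <- nrow(G)
  set.seed(seed)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  sigma_u2 <- h2
  sigma_e2 <- (1 - h2) / mean(1 / weights)
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6) stop("G is not positive semi-definite")
  L <- chol(sigma_u2 * G + diag(1e-8, n))
  u <- if (sigma_u2 > 0) as.numeric(crossprod(L, rnorm(n))) else numeric(n)
  e <- rnorm(n, sd = sqrt(sigma_e2 / weights))
  y <- mu + u + e
  beta <- 0
  if (!is.null(causal_dosage) && causal_var_frac > 0) {
    vx <- var(causal_dosage)
    if (vx <= 0) stop("causal marker is monomorphic")
    beta <- sqrt(causal_var_frac / vx)
    y <- y + causal_dosage * beta
  }
  animals <- rownames(G) %||% sprintf("A%04d", seq_len(n))
  list(phenotypes = data.table(animal = animals, trait = trait, dyd = y,
                               weight = weights),
       truth = list(beta = beta, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2))
}

#' Simulate an array-genotyped deletion panel
#'
#' Emulates the structure of a deletion marker panel carried on a genotyping
#' array: a fixed number of markers of which a few are monomorphic in the
#' genotyped population (failed or reference-specific assays), the rest
#' segregating with a right-skewed minor-allele-frequency distribution
#' (mean MAF ~ 0.17) and mild breed divergence.
#'
#' @param n_markers Total markers on the panel.
#' @param n_monomorphic Markers fixed for the reference allele.
#' @param breeds Breed labels.
#' @param n_per_breed Genotyped animals per breed.
#' @param divergence Balding-Nichols Fst across breeds.
#' @param seed Seed.
#' @return List with `dosages` (animals x markers), `samples`
#'   (`data.table`: `animal`, `breed`) and `monomorphic` (marker ids planted
#'   as monomorphic).
#' @export
simulate_deletion_panel <- function(n_markers = 230L, n_monomorphic = 9L,
                                    breeds = sprintf("B%02d", 1:21),
                                    n_per_breed = 60L, divergence = 0.05,
                                    seed = 1L) {
  stopifnot(n_monomorphic <= n_markers)
  set.seed(seed)
  ids <- sprintf("del%03d", seq_len(n_markers))
  mono <- sample(ids, n_monomorphic)
  maf <- rbeta(n_markers, 2, 9.6)                # mean ~0.17
  maf <- pmin(pmax(maf, 0.01), 0.5)
  maf[ids %in% mono] <- 0
  samples <- rbindlist(lapply(breeds, function(b)
    data.table(animal = sprintf("%s_A%03d", b, seq_len(n_per_breed)), breed = b)))
  n <- nrow(samples)
  dos <- matrix(0L, nrow = n, ncol = n_markers,
                dimnames = list(samples$animal, ids))
  for (j in seq_len(n_markers)) {
    if (maf[j] == 0) next
    fb <- .balding_nichols(maf[j], length(breeds), divergence)
    f <- fb[match(samples$breed, breeds)]
    dos[, j] <- rbinom(n, 2L, f)
  }
  list(dosages = dos, samples = samples, monomorphic = mono)
}
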