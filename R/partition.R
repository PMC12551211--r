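# Node-occupancy accounting over a reference-backbone graph: which samples
# carry which nodes, the core/flexible/nested partition, per-sample novel
# sequence, non-reference sequence (NRS) extraction and breed-specific
# feature totals.

#' Compute node occupancy from sample paths
#'
#' A node's carrier set is exactly the samples whose path steps include it,
#' in either orientation. Reference-backbone membership is recorded
#' separately: the reference is treated as one more carrier of every rank-0
#' node when partitioning.
#'
#' @param graph A [pangenome_graph].
#' @param paths List of [sample_path] objects.
#' @return An `occupancy_table`: list with `node_samples` (long
#'   `data.table` of `node_id`, `sample_id`), `samples` (the sample
#'   universe), `on_reference` and `node_length` (named by node).
#' @export
compute_occupancy <- function(graph, paths) {
  stopifnot(inherits(graph, "pangenome_graph"))
  ns <- rbindlist(lapply(paths, function(p)
    unique(p$steps[, .(node_id)])[, sample_id := p$sample_id]))
  if (!nrow(ns)) ns <- data.table(node_id = character(), sample_id = character())
  unknown <- setdiff(ns$node_id, graph$nodes$node_id)
  if (length(unknown))
    stop("paths reference nodes absent from graph: ",
         paste(head(unknown, 5L), collapse = ", "))
  occ <- list(
    node_samples = ns,
    samples = vapply(paths, function(p) p$sample_id, ""),
    on_reference = setNames(graph$nodes$rank == 0L, graph$nodes$node_id),
    node_length = setNames(as.numeric(graph$nodes$length), graph$nodes$node_id))
  class(occ) <- "occupancy_table"
  occ
}

#' Carrier samples of one node
#' @param occ An `occupancy_table`.
#' @param node A node id.
#' @return Character vector of carrier sample ids (possibly empty).
#' @export
node_carriers <- function(occ, node) {
  occ$node_samples[node_id == node, sample_id]
}

#' Partition graph nodes into core, flexible and nested classes
#'
#' Core nodes are carried by every sample *and* lie on the reference
#' backbone (the reference counts as a carrier); nested nodes are carried by
#' no sample and are off-backbone (realignment artefacts, excluded from
#' downstream analysis); everything else is flexible. Base counts are sums
#' of member node lengths, so core + flexible + nested bases equal the total
#' graph bases, and core + flexible bases equal the path-covered (i.e.
#' non-nested) bases.
#'
#' @param occ An `occupancy_table` over the full sample universe.
#' @param samples Sample universe; defaults to the occupancy table's.
#' @return A `partition_summary`: `data.table` with one row per class
#'   (`class`, `nodes`, `bases`) carrying the membership as attribute
#'   `membership` (named list of node-id vectors).
#' @export
partition_core_flexible <- function(occ, samples = occ$samples) {
  if (!length(samples)) stop("empty sample universe")
  counts <- occ$node_samples[sample_id %in% samples, .N, by = node_id]
  n_carriers <- setNames(rep(0L, length(occ$node_length)), names(occ$node_length))
  n_carriers[counts$node_id] <- counts$N
  on_ref <- occ$on_reference[names(n_carriers)]
  cls <- ifelse(n_carriers == length(samples) & on_ref, "core",
         ifelse(n_carriers == 0L & !on_ref, "nested", "flexible"))
  membership <- split(names(cls), factor(cls, levels = c("core", "flexible", "nested")))
  out <- data.table(
    class = c("core", "flexible", "nested"),
    nodes = vapply(membership, length, 0L),
    bases = vapply(membership, function(m) sum(occ$node_length[m]), 0))
  setattr(out, "membership", membership)
  setattr(out, "class", c("partition_summary", class(out)))
  out
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("graph partition:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s %8d nodes  %15s bases\n", x$class[i], x$nodes[i],
                format(x$bases[i], big.mark = ",")))
  cat(sprintf("  %-8s %8d nodes  %15s bases\n", "total", sum(x$nodes),
              format(sum(x$bases), big.mark = ",")))
  invisible(x)
}

#' Novel (off-backbone) sequence first introduced by each sample
#'
#' Walks the samples in an integration order and credits every carried
#' off-backbone node to the earliest carrier in that order. Contributions
#' sum to the total off-backbone, path-covered bases regardless of the
#' order.
#'
#' @param graph A [pangenome_graph].
#' @param paths List of [sample_path].
#' @param order Integration order; must cover all path samples.
#' @return `data.table` with `sample_id` and `bases`, in `order`.
#' @export
per_sample_novel_contribution <- function(graph, paths,
                                          order = vapply(paths, function(p)
                                            p$sample_id, "")) {
  occ <- compute_occupancy(graph, paths)
  missing <- setdiff(order, occ$samples)
  if (length(missing))
    stop("samples in order but not in occupancy: ",
         paste(missing, collapse = ", "))
  if (length(setdiff(occ$samples, order)))
    stop("order does not cover all samples")
  ns <- occ$node_samples[!occ$on_reference[node_id]]
  ns[, rank_in_order := match(sample_id, order)]
  first <- ns[, .(sample_id = sample_id[which.min(rank_in_order)]), by = node_id]
  first[, bases := occ$node_length[node_id]]
  totals <- first[, .(bases = sum(bases)), by = sample_id]
  out <- data.table(sample_id = order)
  out <- totals[out, on = "sample_id"]
  out[is.na(bases), bases := 0]
  out[]
}

#' Extract non-reference sequences (NRS)
#'
#' Applies the three NRS filters: drop nested nodes (carried by no sample),
#' drop reference-backbone nodes, and keep only sequences strictly longer
#' than `min_len` bases.
#'
#' @param graph A [pangenome_graph].
#' @param occ An `occupancy_table`.
#' @param min_len Length filter in bp (strict `>`).
#' @return List with `node_ids`, `total_bases` and `fasta`
#'   (`DNAStringSet` named by node id; nodes without stored sequence are
#'   omitted from the FASTA but kept in the id set).
#' @export
extract_nrs <- function(graph, occ, min_len = 50L) {
  carried <- unique(occ$node_samples$node_id)
  keep <- graph$nodes[node_id %in% carried & rank > 0L & length > min_len]
  seqs <- keep[!is.na(sequence)]
  list(node_ids = keep$node_id,
       total_bases = sum(as.numeric(keep$length)),
       fasta = Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$node_id)))
}

#' Per-breed totals of breed-specific features
#'
#' A feature (node, SV, insertion...) is breed-specific iff all of its
#' carrier samples belong to a single breed; one carrier within the breed
#' suffices.
#'
#' @param feature_carriers Named list: feature id -> character vector of
#'   carrier sample ids (empty carrier sets are ignored).
#' @param breed_map Named character vector: sample id -> breed.
#' @param feature_lengths Named numeric: feature id -> length in bp.
#' @return `data.table` with `breed`, `n_features`, `bases` (one row per
#'   breed in `breed_map`, zero rows filled in), plus the specific feature
#'   ids as attribute `features`.
#' @export
breed_specific_features <- function(feature_carriers, breed_map, feature_lengths) {
  all_carriers <- unique(unlist(feature_carriers, use.names = FALSE))
  unknown <- setdiff(all_carriers, names(breed_map))
  if (length(unknown))
    stop("carrier samples without breed assignment: ",
         paste(head(unknown, 5L), collapse = ", "))
  rows <- lapply(names(feature_carriers), function(f) {
    carr <- feature_carriers[[f]]
    if (!length(carr)) return(NULL)
    b <- unique(breed_map[carr])
    if (length(b) == 1L)
      data.table(feature = f, breed = b, bases = feature_lengths[[f]])
  })
  spec <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
  out <- data.table(breed = sort(unique(breed_map)))
  if (nrow(spec)) {
    agg <- spec[, .(n_features = .N, bases = sum(bases)), by = breed]
    out <- agg[out, on = "breed"]
    out[is.na(n_features), `:=`(n_features = 0L, bases = 0)]
  } else {
    out[, `:=`(n_features = 0L, bases = 0)]
  }
  setattr(out, "features", if (nrow(spec)) spec$feature else character(0))
  setorder(out, breed)
  out[]
}

utils::globalVariables(c("rank_in_order", "bases", "n_features", "feature", "N"))
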