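# Bubble enumeration along the reference backbone, SV classification and
# genotyping, non-reference unique insertion (NRUI) extraction, and length
# spectra.

#' Project a sample path onto the reference backbone
#'
#' Consecutive backbone nodes visited by the path define anchor pairs; the
#' nodes between them form the traversal (possibly empty). Skipped backbone
#' nodes between two anchors are deletion evidence; off-backbone nodes are
#' insertion/substitution evidence. Backbone visits that break collinearity
#' (out of backbone order) are dropped and the path is flagged.
#'
#' @param path A [sample_path].
#' @param graph A [pangenome_graph].
#' @return `data.table` with one row per anchor pair: `chrom`, `left_idx`,
#'   `right_idx` (backbone indices), `left_node`, `right_node`,
#'   `traversal` (list of node ids strictly between the anchors) and
#'   `deviates` (logical: traversal non-empty or backbone nodes skipped).
#'   Attribute `flagged` is `TRUE` if non-collinear visits were dropped.
#' @export
project_path <- function(path, graph) {
  stopifnot(inherits(path, "sample_path"), inherits(graph, "pangenome_graph"))
  flagged <- FALSE
  out <- lapply(unique(path$steps$chrom), function(ch) {
    bb <- graph$backbone[chrom == ch]
    if (!nrow(bb)) return(NULL)
    st <- path$steps[chrom == ch]
    idx <- match(st$node_id, bb$node_id)          # NA = off-backbone
    vis <- which(!is.na(idx))
    if (!length(vis)) return(NULL)
    keep <- logical(length(vis))
    last <- 0L
    for (k in seq_along(vis)) {
      if (idx[vis[k]] > last) {
        keep[k] <- TRUE
        last <- idx[vis[k]]
      } else flagged <<- TRUE
    }
    vis <- vis[keep]
    if (length(vis) < 2L) return(NULL)
    rbindlist(lapply(seq_len(length(vis) - 1L), function(k) {
      p <- vis[k]; q <- vis[k + 1L]
      trav <- if (q > p + 1L) st$node_id[(p + 1L):(q - 1L)] else character(0)
      data.table(chrom = ch,
                 left_idx = idx[p], right_idx = idx[q],
                 left_node = st$node_id[p], right_node = st$node_id[q],
                 traversal = list(trav),
                 deviates = length(trav) > 0L || idx[q] > idx[p] + 1L)
    }))
  })
  res <- rbindlist(out[!vapply(out, is.null, TRUE)])
  if (flagged)
    message("path ", path$sample_id, ": non-collinear backbone visits dropped")
  setattr(res, "flagged", flagged)
  res[]
}

.concat_seq <- function(graph, node_ids) {
  if (!length(node_ids)) return("")
  s <- graph$nodes[match(node_ids, node_id), sequence]
  if (anyNA(s)) stop("node without stored sequence in traversal")
  paste(s, collapse = "")
}

#' Enumerate bubbles along the reference backbone
#'
#' A bubble is a maximal anchor pair at which at least one sample deviates
#' from the backbone. Deviating anchor intervals from different samples that
#' overlap are merged to their union (logged). Within each bubble, alleles
#' are deduplicated by the concatenated node sequence of the traversal;
#' allele 0 is always the reference path between the anchors. Every sample
#' is assigned an allele, or missing if it does not cover both anchors.
#'
#' @param graph A [pangenome_graph] (node sequences required).
#' @param paths Non-empty list of [sample_path].
#' @return A `bubble_set`: list with `bubbles` (list of bubble records:
#'   `bubble_id`, `chrom`, `left_anchor`, `right_anchor`, `ref_start0`,
#'   `ref_end0`, `alleles` = `data.table(allele_id, seq, len, nodes,
#'   is_ref)`, `carriers` = named integer vector) and `samples`.
#' @export
enumerate_bubbles <- function(graph, paths) {
  stopifnot(length(paths) >= 1L)
  samples <- vapply(paths, function(p) p$sample_id, "")
  proj <- lapply(paths, project_path, graph = graph)
  names(proj) <- samples

  bubbles <- list()
  for (ch in unique(graph$backbone$chrom)) {
    bb <- graph$backbone[chrom == ch]
    events <- rbindlist(lapply(proj, function(pr) pr[chrom == ch & deviates == TRUE]))
    if (!nrow(events)) next
    iv <- unique(events[, .(left_idx, right_idx)])
    setorder(iv, left_idx, right_idx)
    merged <- list(); cur <- iv[1L]
    n_merged <- 0L
    if (nrow(iv) > 1L) for (r in 2L:nrow(iv)) {
      if (iv$left_idx[r] < cur$right_idx) {       # shares affected backbone span
        cur$right_idx <- max(cur$right_idx, iv$right_idx[r])
        n_merged <- n_merged + 1L
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- iv[r]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    if (n_merged > 0L)
      message(ch, ": ", n_merged, " overlapping anchor pair(s) merged to union intervals")

    # per sample: step position of each accepted backbone visit
    visits <- lapply(paths, function(p) {
      st <- p$steps[chrom == ch]
      idx <- match(st$node_id, bb$node_id)
      pos <- which(!is.na(idx))
      keep <- logical(length(pos)); last <- 0L
      for (k in seq_along(pos)) {
        if (idx[pos[k]] > last) { keep[k] <- TRUE; last <- idx[pos[k]] }
      }
      list(steps = st, at = setNames(pos[keep], idx[pos[keep]]))
    })
    names(visits) <- samples

    for (m in merged) {
      L <- m$left_idx; R <- m$right_idx
      inner_bb <- if (R > L + 1L) bb$node_id[(L + 1L):(R - 1L)] else character(0)
      ref_seq <- .concat_seq(graph, inner_bb)
      allele_seqs <- ref_seq
      allele_nodes <- list(inner_bb)
      carriers <- setNames(rep(NA_integer_, length(samples)), samples)
      for (s in samples) {
        v <- visits[[s]]
        pL <- v$at[as.character(L)]; pR <- v$at[as.character(R)]
        if (is.na(pL) || is.na(pR)) next
        trav <- if (pR > pL + 1L) v$steps$node_id[(pL + 1L):(pR - 1L)] else character(0)
        seq <- .concat_seq(graph, trav)
        hit <- match(seq, allele_seqs)
        if (is.na(hit)) {
          allele_seqs <- c(allele_seqs, seq)
          allele_nodes[[length(allele_nodes) + 1L]] <- trav
          hit <- length(allele_seqs)
        }
        carriers[s] <- hit - 1L                   # 0 = reference allele
      }
      bubbles[[length(bubbles) + 1L]] <- list(
        bubble_id = sprintf("bub_%s_%07d", ch, bb$end[L]),
        chrom = ch, left_anchor = bb$node_id[L], right_anchor = bb$node_id[R],
        ref_start0 = bb$end[L], ref_end0 = bb$start[R],
        alleles = data.table(allele_id = seq_along(allele_seqs) - 1L,
                             seq = allele_seqs, len = nchar(allele_seqs),
                             nodes = allele_nodes,
                             is_ref = seq_along(allele_seqs) == 1L),
        carriers = carriers)
    }
  }
  structure(list(bubbles = bubbles, samples = samples), class = "bubble_set")
}

#' @export
print.bubble_set <- function(x, ...) {
  cat(sprintf("bubble_set: %d bubbles over %d samples\n",
              length(x$bubbles), length(x$samples)))
  invisible(x)
}

#' Classify one bubble as a structural variant
#'
#' Allelicity is biallelic iff the bubble holds exactly two allele paths
#' (reference + one alternate). Type rules: an insertion has an (essentially)
#' empty reference path and an alternate of at least `min_sv_len` bases; a
#' deletion has an (essentially) empty alternate path and a reference of at
#' least `min_sv_len` bases; everything else with sequence on both sides is
#' a substitution. Bubbles whose reference and all alternate alleles are
#' shorter than `min_sv_len` are not SVs and are dropped (`NULL`).
#'
#' @param bubble One bubble record from [enumerate_bubbles].
#' @param min_sv_len Minimum allele length for an SV (bp).
#' @param small_allele_tol Maximum length still treated as "no sequence"
#'   when testing the empty side of an insertion/deletion. The strict
#'   definition is 0; a tolerance of up to 5 bp mirrors catalogues that
#'   allow a few residual bases on the empty path.
#' @return A one-row `data.table` (`sv_id`, `chrom`, `start0`, `end0`,
#'   `sv_type`, `allelicity`, `ref_len`, `alt_lens`, `ref_seq`, `alt_seqs`)
#'   or `NULL` if the bubble is below the SV length threshold.
#' @export
classify_sv <- function(bubble, min_sv_len = 50L, small_allele_tol = 0L) {
  al <- bubble$alleles
  if (nrow(al) < 2L)
    stop("bubble ", bubble$bubble_id, " has a single allele; not a variant site")
  ref_len <- al$len[al$is_ref]
  alt_lens <- al$len[!al$is_ref]
  if (ref_len < min_sv_len && all(alt_lens < min_sv_len)) return(NULL)
  sv_type <-
    if (ref_len <= small_allele_tol && max(alt_lens) >= min_sv_len) "INS"
    else if (min(alt_lens) <= small_allele_tol && ref_len >= min_sv_len) "DEL"
    else "SUB"
  data.table(
    sv_id = bubble$bubble_id, chrom = bubble$chrom,
    start0 = bubble$ref_start0, end0 = bubble$ref_end0,
    sv_type = sv_type,
    allelicity = if (nrow(al) == 2L) "biallelic" else "multiallelic",
    ref_len = ref_len, alt_lens = list(alt_lens),
    ref_seq = al$seq[al$is_ref], alt_seqs = list(al$seq[!al$is_ref]))
}

#' Classify every bubble and assemble the SV catalogue
#'
#' @param bubble_set A `bubble_set` from [enumerate_bubbles].
#' @inheritParams classify_sv
#' @return An `sv_catalog`: list with `svs` (`data.table`, one row per
#'   retained SV) and `genotypes` (samples x SVs matrix of haploid allele
#'   indices; 0 = reference, `NA` = site not covered).
#' @export
classify_sv_catalog <- function(bubble_set, min_sv_len = 50L,
                                small_allele_tol = 0L) {
  rows <- list(); gts <- list()
  for (b in bubble_set$bubbles) {
    r <- classify_sv(b, min_sv_len = min_sv_len,
                     small_allele_tol = small_allele_tol)
    if (is.null(r)) next
    rows[[length(rows) + 1L]] <- r
    gts[[length(gts) + 1L]] <- b$carriers
  }
  svs <- if (length(rows)) rbindlist(rows) else
    data.table(sv_id = character(), chrom = character(), start0 = integer(),
               end0 = integer(), sv_type = character(), allelicity = character(),
               ref_len = integer(), alt_lens = list(), ref_seq = character(),
               alt_seqs = list())
  gt <- if (length(gts)) do.call(cbind, gts) else
    matrix(NA_integer_, nrow = length(bubble_set$samples), ncol = 0,
           dimnames = list(bubble_set$samples, NULL))
  colnames(gt) <- svs$sv_id
  structure(list(svs = svs, genotypes = gt), class = "sv_catalog")
}

#' @export
print.sv_catalog <- function(x, ...) {
  tab <- table(x$svs$sv_type)
  cat(sprintf("sv_catalog: %d SVs (%s) over %d samples\n", nrow(x$svs),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              nrow(x$genotypes)))
  invisible(x)
}

#' Extract non-reference unique insertions (NRUIs)
#'
#' NRUIs are drawn only from insertion-type bubbles that contain no
#' reference-derived node (the reference path between the anchors is empty),
#' keeping inserted nodes strictly longer than `min_len`. By construction
#' NRUI nodes are a subset of the NRS node set.
#'
#' @param bubble_set A `bubble_set`.
#' @param graph The [pangenome_graph] (for node sequences and lengths).
#' @inheritParams classify_sv
#' @param min_len Length filter in bp (strict `>`).
#' @return List with `node_ids`, `total_bases`, `fasta` (`DNAStringSet`)
#'   and `carriers` (named list: node id -> carrier samples).
#' @export
extract_nrui <- function(bubble_set, graph, min_len = 50L, min_sv_len = 50L,
                         small_allele_tol = 0L) {
  ids <- character(0); carriers <- list()
  for (b in bubble_set$bubbles) {
    r <- classify_sv(b, min_sv_len = min_sv_len,
                     small_allele_tol = small_allele_tol)
    if (is.null(r) || r$sv_type != "INS") next
    if (length(b$alleles$nodes[[which(b$alleles$is_ref)]])) next  # ref node inside
    for (k in which(!b$alleles$is_ref)) {
      samp <- names(b$carriers)[!is.na(b$carriers) &
                                  b$carriers == b$alleles$allele_id[k]]
      for (nid in b$alleles$nodes[[k]]) {
        if (graph$nodes[node_id == nid, length] > min_len) {
          ids <- c(ids, nid)
          carriers[[nid]] <- sort(unique(c(carriers[[nid]], samp)))
        }
      }
    }
  }
  ids <- unique(ids)
  seqs <- graph$nodes[node_id %in% ids & !is.na(sequence)]
  list(node_ids = ids,
       total_bases = sum(as.numeric(graph$nodes[node_id %in% ids, length])),
       fasta = Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$node_id)),
       carriers = carriers)
}

#' Length spectrum of an SV catalogue
#'
#' Event length is the alternate-allele length for insertions, the
#' reference-allele length for deletions, and the longer of the two for
#' substitutions (the longest alternate at multiallelic sites).
#'
#' @param catalog An `sv_catalog`.
#' @param type Optional subset of `"INS"`, `"DEL"`, `"SUB"`.
#' @param bin_width Histogram bin width in bp.
#' @return `data.table` with `sv_type`, `bin_start` (bp, left-closed) and
#'   `count`; bin counts sum to the number of records considered.
#' @export
length_spectrum <- function(catalog, type = NULL, bin_width = 50L) {
  svs <- catalog$svs
  if (!is.null(type)) svs <- svs[sv_type %in% type]
  if (!nrow(svs))
    return(data.table(sv_type = character(), bin_start = integer(),
                      count = integer()))
  len <- vapply(seq_len(nrow(svs)), function(i) {
    switch(svs$sv_type[i],
           INS = max(svs$alt_lens[[i]]),
           DEL = svs$ref_len[i],
           SUB = max(svs$ref_len[i], max(svs$alt_lens[[i]])))
  }, 0)
  dt <- data.table(sv_type = svs$sv_type,
                   bin_start = as.integer(floor(len / bin_width) * bin_width))
  dt[, .(count = .N), by = .(sv_type, bin_start)][order(sv_type, bin_start)]
}

utils::globalVariables(c("left_idx", "right_idx", "deviates", "bin_start",
                         "count", "len"))
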