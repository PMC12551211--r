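# Readers/writers for the formats the pipeline touches: rGFA/GFA1 graphs,
# per-assembly node-path BED files, FASTA, a structural-variant VCF, and the
# genotype/phenotype/metadata tables used downstream.
#
# Internal coordinates are 0-based half-open throughout; VCF emission converts
# to 1-based anchored positions.

#' Construct a reference-backbone pangenome graph
#'
#' The container mirrors the structure produced by reference-backed graph
#' builders: segments (nodes) carrying a DNA sequence, a rank (0 for the
#' linear reference backbone, >0 for sequence introduced by later assemblies)
#' and an origin (`sn` contig, `so` offset), plus oriented links between
#' consecutive segments. Rank-0 nodes, ordered by origin offset, form the
#' per-chromosome backbone with cumulative reference coordinates.
#'
#' @param nodes `data.table` with columns `node_id`, `sequence` (uppercase
#'   DNA, may be `NA` if only a length is known), `length`, `rank`,
#'   `sn` (origin contig; required for rank-0 nodes), `so` (origin offset).
#' @param edges `data.table` with columns `from`, `from_orient`, `to`,
#'   `to_orient`; orientations are `"+"` or `"-"`.
#' @return An object of class `pangenome_graph` with elements `nodes`,
#'   `edges` and `backbone` (a `data.table` of rank-0 nodes with `chrom`,
#'   `node_id`, `start`, `end` reference coordinates, 0-based half-open).
#' @export
pangenome_graph <- function(nodes, edges) {
  nodes <- as.data.table(nodes)
  edges <- as.data.table(edges)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node_id in graph: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  has_seq <- !is.na(nodes$sequence)
  bad <- has_seq & nodes$length != nchar(nodes$sequence)
  if (any(bad))
    stop("node length disagrees with sequence length for: ",
         paste(nodes$node_id[bad], collapse = ", "))
  if (nrow(edges)) {
    known <- c(edges$from, edges$to) %in% nodes$node_id
    if (!all(known))
      stop("edge endpoint not in node set: ",
           paste(unique(c(edges$from, edges$to)[!known]), collapse = ", "))
    if (!all(c(edges$from_orient, edges$to_orient) %in% c("+", "-")))
      stop("edge orientations must be '+' or '-'")
  }
  bb <- nodes[rank == 0L]
  if (nrow(bb)) {
    if (any(is.na(bb$sn)) || any(is.na(bb$so)))
      stop("rank-0 nodes require origin (sn/so) tags to assemble the backbone")
    setorder(bb, sn, so)
    backbone <- bb[, {
      if (any(diff(so) <= 0))
        stop("rank-0 nodes with non-increasing offsets on ", sn[1L])
      if (any(so[-1L] < (so + length)[-.N]))
        stop("rank-0 nodes with overlapping offsets on ", sn[1L])
      list(node_id = node_id, start = so, end = so + length)
    }, by = .(chrom = sn)]
  } else {
    backbone <- data.table(chrom = character(), node_id = character(),
                           start = integer(), end = integer())
  }
  g <- list(nodes = nodes, edges = edges, backbone = backbone)
  class(g) <- "pangenome_graph"
  g
}

#' @export
print.pangenome_graph <- function(x, ...) {
  cat(sprintf(
    "pangenome_graph: %d nodes (%s bp), %d edges, backbone %d nodes on %d chromosome(s)\n",
    nrow(x$nodes), format(sum(as.numeric(x$nodes$length)), big.mark = ","),
    nrow(x$edges), nrow(x$backbone), length(unique(x$backbone$chrom))))
  invisible(x)
}

.parse_gfa_tags <- function(fields) {
  tags <- list(sn = NA_character_, so = NA_integer_, sr = NA_integer_, ln = NA_integer_)
  for (f in fields) {
    if (startsWith(f, "SN:Z:")) tags$sn <- substring(f, 6L)
    else if (startsWith(f, "SO:i:")) tags$so <- as.integer(substring(f, 6L))
    else if (startsWith(f, "SR:i:")) tags$sr <- as.integer(substring(f, 6L))
    else if (startsWith(f, "LN:i:")) tags$ln <- as.integer(substring(f, 6L))
  }
  tags
}

#' Read an rGFA / GFA1 graph
#'
#' Parses S and L lines. Segment origin tags (`SN:Z`, `SO:i`, `SR:i`) are
#' required on rank-0 (reference) segments so that the backbone can be
#' assembled, and optional elsewhere; `SR` defaults to rank 1 for untagged
#' segments. A segment may carry `*` in place of its sequence if an `LN:i`
#' tag gives its length.
#'
#' Plain GFA1 without any rGFA tags is accepted: if `backbone` names an
#' ordered set of segments they become the rank-0 reference path (offsets
#' from the prefix sums of their lengths); with no `backbone` every
#' untagged segment is treated as its own single-node reference contig.
#'
#' @param path Path to a GFA file.
#' @param backbone Optional ordered character vector of segment ids forming
#'   the reference path of a tag-free GFA1 file.
#' @return A [pangenome_graph].
#' @export
read_gfa <- function(path, backbone = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  s_rows <- list()
  l_rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, "H")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (fields[1L] == "S") {
      if (length(fields) < 3L)
        stop("malformed S line at line ", i, " of ", path)
      seq <- fields[3L]
      tags <- .parse_gfa_tags(fields[-(1:3)])
      if (identical(seq, "*")) {
        if (is.na(tags$ln))
          stop("S line without sequence or LN tag at line ", i, " of ", path)
        len <- tags$ln
        seq <- NA_character_
      } else {
        seq <- toupper(seq)
        len <- nchar(seq)
      }
      s_rows[[length(s_rows) + 1L]] <- data.table(
        node_id = fields[2L], sequence = seq, length = len,
        rank = tags$sr, sn = tags$sn, so = tags$so)
    } else if (fields[1L] == "L") {
      if (length(fields) < 6L)
        stop("malformed L line at line ", i, " of ", path)
      l_rows[[length(l_rows) + 1L]] <- data.table(
        from = fields[2L], from_orient = fields[3L],
        to = fields[4L], to_orient = fields[5L])
    }
  }
  nodes <- if (length(s_rows)) rbindlist(s_rows) else
    data.table(node_id = character(), sequence = character(), length = integer(),
               rank = integer(), sn = character(), so = integer())
  edges <- if (length(l_rows)) rbindlist(l_rows) else
    data.table(from = character(), from_orient = character(),
               to = character(), to_orient = character())
  if (!is.null(backbone)) {
    miss <- setdiff(backbone, nodes$node_id)
    if (length(miss)) stop("backbone segments not in GFA: ",
                           paste(miss, collapse = ", "))
    idx <- match(backbone, nodes$node_id)
    nodes[idx, `:=`(rank = 0L, sn = "ref",
                    so = cumsum(c(0L, nodes$length[idx]))[seq_along(idx)])]
    nodes[is.na(rank), rank := 1L]
  } else if (all(is.na(nodes$rank)) && nrow(nodes)) {
    # tag-free GFA1: each segment its own reference contig
    nodes[, `:=`(rank = 0L,
                 sn = ifelse(is.na(sn), node_id, sn),
                 so = ifelse(is.na(so), 0L, so))]
  } else {
    nodes[is.na(rank), rank := 1L]
  }
  pangenome_graph(nodes, edges)
}

#' Write a pangenome graph as rGFA
#'
#' Emits one S line per node (with `SN`/`SO`/`SR` tags where known) and one
#' L line per edge (overlap `0M`, the no-overlap convention of
#' reference-backed graphs). Re-reading the file with [read_gfa] restores an
#' identical graph.
#'
#' @param graph A [pangenome_graph].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "pangenome_graph"))
  n <- graph$nodes
  tag <- function(prefix, x) ifelse(is.na(x), "", paste0("\t", prefix, x))
  s_lines <- paste0(
    "S\t", n$node_id, "\t",
    ifelse(is.na(n$sequence), "*", n$sequence),
    ifelse(is.na(n$sequence), paste0("\tLN:i:", n$length), ""),
    tag("SN:Z:", n$sn), tag("SO:i:", n$so), tag("SR:i:", n$rank))
  e <- graph$edges
  l_lines <- if (nrow(e))
    paste0("L\t", e$from, "\t", e$from_orient, "\t", e$to, "\t", e$to_orient, "\t0M")
  else character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(s_lines, l_lines), con)
  invisible(path)
}

#' Construct a sample path (one assembly's walk through the graph)
#'
#' @param sample_id Sample identifier.
#' @param steps `data.table` with columns `chrom`, `node_id`, `orient`,
#'   ordered as the assembly traverses the graph.
#' @param covered Optional `data.table` of reference intervals
#'   (`chrom`, `start`, `end`; 0-based half-open) the path is anchored to.
#' @param breed Optional breed label.
#' @return An object of class `sample_path`.
#' @export
sample_path <- function(sample_id, steps, covered = NULL, breed = NA_character_) {
  steps <- as.data.table(steps)
  p <- list(sample_id = sample_id, breed = breed, steps = steps,
            covered = if (is.null(covered)) steps[0L, .(chrom, start = integer(),
                                                        end = integer())] else
              as.data.table(covered))
  class(p) <- "sample_path"
  p
}

#' @export
print.sample_path <- function(x, ...) {
  cat(sprintf("sample_path %s (%s): %d steps on %d chromosome(s)\n",
              x$sample_id, x$breed, nrow(x$steps), length(unique(x$steps$chrom))))
  invisible(x)
}

.edge_keys <- function(edges) {
  flip <- function(o) ifelse(o == "+", "-", "+")
  c(paste(edges$from, edges$from_orient, edges$to, edges$to_orient),
    paste(edges$to, flip(edges$to_orient), edges$from, flip(edges$from_orient)))
}

#' Read a per-sample node-path BED file
#'
#' One line per covered reference interval: `chrom  start  end  sample
#' node_list`, with `node_list` a comma-separated sequence of oriented node
#' ids (e.g. `s1+,s12+,s3+`). Node references are validated against the
#' graph, and consecutive steps must correspond to a graph edge.
#'
#' @param path Path to the BED file; an empty file yields an empty path.
#' @param graph The [pangenome_graph] the path walks through.
#' @param breed Optional breed label attached to the path.
#' @return A [sample_path].
#' @export
read_path_bed <- function(path, graph, breed = NA_character_) {
  stopifnot(inherits(graph, "pangenome_graph"))
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(sample_path(sub("\\.bed$", "", basename(path)),
                       data.table(chrom = character(), node_id = character(),
                                  orient = character()), breed = breed))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L)) stop("malformed path BED line in ", path)
  sample_id <- unique(vapply(parts, `[`, "", 4L))
  if (length(sample_id) != 1L) stop("multiple sample ids in ", path)
  step_list <- lapply(parts, function(f) {
    toks <- strsplit(f[5L], ",", fixed = TRUE)[[1]]
    data.table(chrom = f[1L],
               node_id = sub("[+-]$", "", toks),
               orient = sub("^.*([+-])$", "\\1", toks))
  })
  steps <- rbindlist(step_list)
  unknown <- setdiff(steps$node_id, graph$nodes$node_id)
  if (length(unknown))
    stop("path references nodes absent from graph: ",
         paste(head(unknown, 5L), collapse = ", "))
  keys <- .edge_keys(graph$edges)
  for (st in step_list) {
    if (nrow(st) < 2L) next
    k <- paste(st$node_id[-nrow(st)], st$orient[-nrow(st)],
               st$node_id[-1L], st$orient[-1L])
    if (!all(k %in% keys))
      stop("path step pair lacking a graph edge: ", k[which(!(k %in% keys))[1L]])
  }
  covered <- rbindlist(lapply(parts, function(f)
    data.table(chrom = f[1L], start = as.integer(f[2L]), end = as.integer(f[3L]))))
  sample_path(sample_id, steps, covered, breed = breed)
}

#' Write a sample path as a node-path BED file
#'
#' Inverse of [read_path_bed]; one line per covered interval.
#'
#' @param path_obj A [sample_path].
#' @param file Output file path.
#' @return `file`, invisibly.
#' @export
write_path_bed <- function(path_obj, file) {
  stopifnot(inherits(path_obj, "sample_path"))
  chroms <- unique(path_obj$steps$chrom)
  lines <- vapply(chroms, function(ch) {
    st <- path_obj$steps[chrom == ch]
    cov <- path_obj$covered[chrom == ch]
    start <- if (nrow(cov)) min(cov$start) else 0L
    end <- if (nrow(cov)) max(cov$end) else 0L
    paste(ch, start, end, path_obj$sample_id,
          paste0(st$node_id, st$orient, collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

# ---- SV VCF ----------------------------------------------------------------

#' Write a structural-variant catalogue as VCF 4.2
#'
#' Positions follow the VCF anchored-allele convention: `POS` is the base
#' immediately before the event and both `REF` and every `ALT` start with
#' that shared anchor base. `INFO` carries `SVTYPE` (INS/DEL/SUB), `SVLEN`
#' and `ALLELICITY`. Assembly genotypes are haploid path calls, written as a
#' single allele index; samples not covering the site are written as
#' missing. `REF` is checked against the reference sequence.
#'
#' @param catalog An `sv_catalog` (see [classify_sv_catalog]) or a
#'   compatible list with elements `svs` and `genotypes`.
#' @param reference Named character vector or `DNAStringSet` of reference
#'   chromosome sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(catalog, reference, path) {
  svs <- as.data.table(catalog$svs)
  gt <- catalog$genotypes
  if (inherits(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  samples <- rownames(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Alt minus ref allele length\">",
    "##INFO=<ID=ALLELICITY,Number=1,Type=String,Description=\"biallelic or multiallelic\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid path genotype\">",
    paste0(sprintf("##contig=<ID=%s,length=%d>", names(reference),
                   nchar(reference)), collapse = "\n"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(svs)), function(i) {
    sv <- svs[i]
    if (sv$start0 < 1L)
      stop("event at chromosome start has no anchor base: ", sv$sv_id)
    anchor <- substr(reference[[sv$chrom]], sv$start0, sv$start0)
    ref_allele <- paste0(anchor, sv$ref_seq)
    seen <- substr(reference[[sv$chrom]], sv$start0, sv$start0 + nchar(ref_allele) - 1L)
    if (!identical(seen, ref_allele))
      stop("REF allele disagrees with reference FASTA for ", sv$sv_id,
           " at ", sv$chrom, ":", sv$start0)
    alts <- paste0(anchor, sv$alt_seqs[[1]])
    svlen <- nchar(alts) - nchar(ref_allele)
    g <- gt[, i]
    gt_str <- ifelse(is.na(g), ".", as.character(g))
    paste(c(sv$chrom, sv$start0, sv$sv_id, ref_allele,
            paste(alts, collapse = ","), ".", "PASS",
            sprintf("SVTYPE=%s;SVLEN=%s;ALLELICITY=%s", sv$sv_type,
                    paste(svlen, collapse = ","), sv$allelicity),
            "GT", gt_str), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a structural-variant VCF written by [write_vcf]
#'
#' @param path VCF file path.
#' @return List with `svs` (`data.table`: `sv_id`, `chrom`, `start0`,
#'   `end0`, `sv_type`, `allelicity`, `ref_seq`, `alt_seqs`) and
#'   `genotypes` (samples x sites matrix of haploid allele indices,
#'   `NA` = missing).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop("no #CHROM header in ", path)
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  rows <- lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    info <- strsplit(f[8L], ";", fixed = TRUE)[[1]]
    get_info <- function(key) {
      hit <- info[startsWith(info, paste0(key, "="))]
      if (length(hit)) sub(paste0(key, "="), "", hit[1L]) else NA_character_
    }
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1]]
    ref_seq <- substring(f[4L], 2L)
    g <- f[-(1:9)]
    list(sv_id = f[3L], chrom = f[1L], start0 = as.integer(f[2L]),
         end0 = as.integer(f[2L]) + nchar(ref_seq),
         sv_type = get_info("SVTYPE"), allelicity = get_info("ALLELICITY"),
         ref_seq = ref_seq, alt_seqs = list(substring(alts, 2L)),
         gt = list(suppressWarnings(as.integer(ifelse(g == ".", NA, g)))))
  })
  svs <- rbindlist(lapply(rows, function(r) r[setdiff(names(r), "gt")]))
  gt <- do.call(cbind, lapply(rows, function(r) r$gt[[1]]))
  rownames(gt) <- samples
  colnames(gt) <- svs$sv_id
  list(svs = svs, genotypes = gt)
}

# ---- tables ----------------------------------------------------------------

.vcf_gt_to_dosage <- function(gt) {
  # "0/1", "1|0", "1", "./." -> copies of the alt allele
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == "." | a == "")) return(NA_real_)
    sum(as.numeric(a) > 0)
  }, 0)
}

#' Read genotype, phenotype and breed-metadata tables
#'
#' The genotype input is either a TSV with columns `marker_id`, `chrom`,
#' `pos` followed by one dosage column per sample (0/1/2, `NA` missing), or
#' a VCF whose `GT` fields are converted to alt-allele dosages. Phenotypes
#' are a TSV `animal`, `trait`, `dyd`, `weight` (daughter yield deviations
#' with per-animal accuracy weights); metadata a TSV `sample`, `breed`.
#' Animals with phenotypes but no genotypes are dropped with a warning.
#'
#' @param genotypes,phenotypes,metadata File paths. `phenotypes` and
#'   `metadata` may be `NULL`.
#' @return List with `dosages` (samples x markers numeric matrix), `markers`
#'   (`data.table` of `marker_id`, `chrom`, `pos`), `phenotypes`
#'   (`data.table`) and `breeds` (named character vector).
#' @export
read_tables <- function(genotypes, phenotypes = NULL, metadata = NULL) {
  first <- readLines(genotypes, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(genotypes)
    hdr <- strsplit(lines[startsWith(lines, "#CHROM")][1L], "\t")[[1]]
    samples <- hdr[-(1:9)]
    body <- lines[!startsWith(lines, "#")]
    f <- strsplit(body, "\t", fixed = TRUE)
    markers <- data.table(
      marker_id = vapply(f, `[`, "", 3L),
      chrom = vapply(f, `[`, "", 1L),
      pos = as.integer(vapply(f, `[`, "", 2L)))
    dos <- t(vapply(f, function(x) .vcf_gt_to_dosage(x[-(1:9)]),
                    numeric(length(samples))))
    dosages <- t(dos)
    dimnames(dosages) <- list(samples, markers$marker_id)
  } else {
    tab <- fread(genotypes)
    stopifnot(all(c("marker_id", "chrom", "pos") %in% names(tab)))
    samples <- setdiff(names(tab), c("marker_id", "chrom", "pos"))
    markers <- tab[, .(marker_id, chrom, pos)]
    dosages <- t(as.matrix(tab[, ..samples]))
    colnames(dosages) <- markers$marker_id
  }
  if (!all(dosages %in% c(0, 1, 2) | is.na(dosages)))
    stop("dosages must be coded 0/1/2 with NA for missing")
  pheno <- NULL
  if (!is.null(phenotypes)) {
    pheno <- fread(phenotypes)
    stopifnot(all(c("animal", "trait", "dyd", "weight") %in% names(pheno)))
    absent <- setdiff(unique(pheno$animal), rownames(dosages))
    if (length(absent)) {
      warning(length(absent), " phenotyped animal(s) without genotypes excluded: ",
              paste(head(absent, 5L), collapse = ", "))
      pheno <- pheno[!animal %in% absent]
    }
  }
  breeds <- NULL
  if (!is.null(metadata)) {
    meta <- fread(metadata)
    stopifnot(all(c("sample", "breed") %in% names(meta)))
    breeds <- setNames(meta$breed, meta$sample)
  }
  list(dosages = dosages, markers = markers, phenotypes = pheno, breeds = breeds)
}

utils::globalVariables(c("..samples", "animal"))
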