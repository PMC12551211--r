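# Conversion of deletions into array-genotypable "virtual SNPs" via the
# breakpoint base-change test, plus marker informativeness statistics
# (MAF, expected heterozygosity He = 2pq, PIC = He - 2 p^2 q^2).

#' Convert a deletion into a virtual SNP
#'
#' Coordinates are 1-based inclusive: the deleted region is `[s, e]` on the
#' reference. The forward test compares the first deleted base (`base(s)`)
#' with the first base after the 3' breakpoint (`base(e + 1)`); if they
#' differ, the deletion is genotypable as a SNP whose reference allele is
#' `base(s)` and whose alternate allele is `base(e + 1)`. A complementary
#' test on the opposite strand compares `base(e)` with `base(s - 1)`; both
#' flags are reported so the caller can require confirmation. The forward
#' test of the reverse-complemented sequence (with mirrored coordinates)
#' equals the reverse test of the original.
#'
#' @param ref_seq Reference chromosome sequence (character or `DNAString`).
#' @param s,e Deletion interval, 1-based inclusive, with `1 < s <= e <
#'   nchar(ref_seq)` so both flanks exist.
#' @param sv_id Optional identifier carried through.
#' @param chrom Optional chromosome name carried through.
#' @return A one-row `data.table`: `sv_id`, `chrom`, `s`, `e`, `ref_allele`,
#'   `alt_allele`, `forward_convertible`, `reverse_confirmed`, `reason`
#'   (`NA` when convertible; otherwise why not).
#' @export
convert_deletion <- function(ref_seq, s, e, sv_id = NA_character_,
                             chrom = NA_character_) {
  ref_seq <- as.character(ref_seq)
  n <- nchar(ref_seq)
  res <- data.table(sv_id = sv_id, chrom = chrom, s = as.integer(s),
                    e = as.integer(e), ref_allele = NA_character_,
                    alt_allele = NA_character_, forward_convertible = FALSE,
                    reverse_confirmed = FALSE, reason = NA_character_)
  if (!(s >= 1 && e >= s && e <= n)) stop("invalid deletion interval")
  if (s <= 1 || e >= n) {
    res$reason <- "interval touches sequence end; no flanking base"
    return(res)
  }
  base <- function(i) substr(ref_seq, i, i)
  b_s <- base(s); b_e1 <- base(e + 1)
  b_e <- base(e); b_s1 <- base(s - 1)
  if (!all(c(b_s, b_e1, b_e, b_s1) %in% c("A", "C", "G", "T"))) {
    res$reason <- "ambiguity base at a tested position"
    return(res)
  }
  res$ref_allele <- b_s
  res$alt_allele <- b_e1
  res$forward_convertible <- b_s != b_e1
  res$reverse_confirmed <- b_e != b_s1
  if (!res$forward_convertible)
    res$reason <- "first deleted base equals first base after the 3' breakpoint"
  res
}

#' Convert every deletion in an SV catalogue
#'
#' @param catalog An `sv_catalog` (only `DEL` records are converted).
#' @param reference Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return `data.table` with one row per deletion (see [convert_deletion]).
#' @export
convert_deletions <- function(catalog, reference) {
  if (inherits(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  dels <- catalog$svs[sv_type == "DEL"]
  if (!nrow(dels))
    return(convert_deletion("ACGTACGTAC", 3, 4)[0L])
  rbindlist(lapply(seq_len(nrow(dels)), function(i)
    convert_deletion(reference[[dels$chrom[i]]],
                     s = dels$start0[i] + 1L,    # 0-based half-open -> 1-based incl.
                     e = dels$end0[i],
                     sv_id = dels$sv_id[i], chrom = dels$chrom[i])))
}

#' Marker informativeness statistics from a dosage vector
#'
#' Allele frequencies are counted over non-missing diploid dosages (0/1/2
#' copies of the alternate allele). `He = 2pq`, `PIC = He - 2 p^2 q^2`,
#' `MAF = min(p, q)`. Monomorphic markers get `He = PIC = 0` and are
#' flagged.
#'
#' @param dosages Numeric vector of 0/1/2 with `NA` for missing; at least
#'   one non-missing call.
#' @param marker_id Optional identifier.
#' @return One-row `data.table`: `marker_id`, `n_called`, `p` (alternate
#'   allele frequency), `q`, `maf`, `he`, `pic`, `monomorphic`.
#' @export
marker_stats <- function(dosages, marker_id = NA_character_) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all genotypes missing for marker ", marker_id)
  d <- dosages[ok]
  stopifnot(all(d %in% 0:2))
  p <- sum(d) / (2 * length(d))
  q <- 1 - p
  he <- 2 * p * q
  data.table(marker_id = marker_id, n_called = length(d), p = p, q = q,
             maf = min(p, q), he = he, pic = he - 2 * p^2 * q^2,
             monomorphic = p == 0 || q == 0)
}

#' Marker statistics for every column of a dosage matrix
#'
#' @param dosages Samples x markers matrix of 0/1/2 dosages.
#' @return `data.table`, one row per marker (see [marker_stats]).
#' @export
marker_stats_matrix <- function(dosages) {
  ids <- colnames(dosages) %||% sprintf("m%d", seq_len(ncol(dosages)))
  rbindlist(lapply(seq_len(ncol(dosages)), function(j)
    marker_stats(dosages[, j], ids[j])))
}

#' Panel-level summary of marker informativeness, overall and by breed
#'
#' Means of MAF, He and PIC are computed over markers polymorphic in the
#' full genotyped set (both alleles observed at least once); the
#' monomorphic count is reported separately. Breeds with no genotyped
#' animals are excluded with a message.
#'
#' @param dosages Samples x markers dosage matrix.
#' @param breed_map Named character vector: sample -> breed.
#' @return List with `overall` (one-row `data.table`: `n_markers`,
#'   `n_polymorphic`, `n_monomorphic`, `mean_maf`, `mean_he`, `mean_pic`),
#'   `by_breed` (`data.table`, same means within breed over the globally
#'   polymorphic markers) and `stats` (per-marker table).
#' @export
panel_summary <- function(dosages, breed_map = NULL) {
  stats <- marker_stats_matrix(dosages)
  poly <- stats[monomorphic == FALSE]
  overall <- data.table(
    n_markers = nrow(stats), n_polymorphic = nrow(poly),
    n_monomorphic = sum(stats$monomorphic),
    mean_maf = mean(poly$maf), mean_he = mean(poly$he),
    mean_pic = mean(poly$pic))
  by_breed <- NULL
  if (!is.null(breed_map)) {
    keep_markers <- poly$marker_id
    rows <- lapply(sort(unique(breed_map)), function(b) {
      animals <- intersect(rownames(dosages), names(breed_map)[breed_map == b])
      if (!length(animals)) {
        message("breed ", b, " has no genotyped animals; excluded")
        return(NULL)
      }
      st <- marker_stats_matrix(dosages[animals, keep_markers, drop = FALSE])
      data.table(breed = b, n_animals = length(animals),
                 mean_maf = mean(st$maf), mean_he = mean(st$he),
                 mean_pic = mean(st$pic))
    })
    by_breed <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
  }
  list(overall = overall, by_breed = by_breed, stats = stats)
}

utils::globalVariables(c("monomorphic", "maf", "he", "pic"))
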