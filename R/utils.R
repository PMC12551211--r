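#' @importFrom data.table data.table setkey setkeyv rbindlist as.data.table := .N .SD setorder setattr fread fwrite
#' @importFrom stats optimize pchisq prcomp cutree hclust dist cor kmeans rnorm runif rbinom rbeta rlnorm var sd setNames
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  "node_id", "rank", "so", "sn", "length", "sample_id", "node", "breed",
  "chrom", "start", "end", "orient", "on_reference", "n_carriers", "sv_type",
  "allelicity", "p_value", "neg_log10_p", "pos", "marker_id", "is_ref",
  "allele_id", "seq_len", "carried", "sequence", "first_carrier", "J",
  "region", "alt_len", "ref_len", "bubble_id", "."
))

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Length of a 1-based inclusive genomic interval
#'
#' Convenience used throughout for intervals reported in 1-based inclusive
#' coordinates (the convention of deletion breakpoint tables).
#'
#' @param s,e Start and end positions, 1-based inclusive, `e >= s`.
#' @return Integer length `e - s + 1`.
#' @export
interval_length_1based <- function(s, e) {
  stopifnot(all(e >= s))
  as.numeric(e) - as.numeric(s) + 1
}

#' Fraction of a count over a total, as a percentage
#'
#' Accounting helper used for catalogue composition summaries (share of
#' biallelic sites, share of insertions among biallelic indels, share of
#' non-reference bases in a graph, ...).
#'
#' @param count Numerator count (or vector of counts).
#' @param total Denominator.
#' @param digits Rounding applied to the percentage; `NULL` for none.
#' @return Percentage on the 0-100 scale.
#' @export
count_share_pct <- function(count, total, digits = 1) {
  stopifnot(total > 0)
  pct <- 100 * count / total
  if (!is.null(digits)) pct <- round(pct, digits)
  pct
}

`%||%` <- function(a, b) if (is.null(a)) b else a
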