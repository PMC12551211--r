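# Population-structure analysis: presence/absence-variation matrices,
# hierarchical clustering of samples, PCA of genotype dosages, and cluster
# agreement with breed labels.

#' Build a presence/absence-variation (PAV) matrix
#'
#' @param feature_carriers Named list: feature id -> carrier sample ids
#'   (must be a subset of `samples`).
#' @param samples Sample universe (matrix row order).
#' @return Binary samples x features matrix; columns that are all-0 or
#'   all-1 are kept but listed in attribute `uninformative`.
#' @export
build_pav <- function(feature_carriers, samples) {
  bad <- setdiff(unique(unlist(feature_carriers, use.names = FALSE)), samples)
  if (length(bad))
    stop("carriers outside the sample universe: ", paste(head(bad, 5), collapse = ", "))
  m <- matrix(0L, nrow = length(samples), ncol = length(feature_carriers),
              dimnames = list(samples, names(feature_carriers)))
  for (f in names(feature_carriers)) m[feature_carriers[[f]], f] <- 1L
  cs <- colSums(m)
  attr(m, "uninformative") <- colnames(m)[cs == 0L | cs == nrow(m)]
  m
}

#' Hierarchical clustering of samples from a PAV matrix
#'
#' Distances default to Jaccard (shared absences are uninformative for
#' presence data) with complete linkage. Rows are ordered lexicographically
#' by sample id before clustering so ties break deterministically. Cutting
#' the tree at `k` yields flat cluster labels.
#'
#' @param pav Binary samples x features matrix.
#' @param k Number of flat clusters (e.g. the number of breeds); `NULL` to
#'   skip cutting.
#' @param distance `"jaccard"` (via `dist(method = "binary")`) or any
#'   method accepted by [stats::dist].
#' @param linkage Agglomeration method for [stats::hclust].
#' @return List with `tree` (`hclust`), `labels` (named integer vector at
#'   `k`, or `NULL`) and `dist`.
#' @export
hcluster_pav <- function(pav, k = NULL, distance = "jaccard",
                         linkage = "complete") {
  stopifnot(nrow(pav) >= 2L)
  pav <- pav[order(rownames(pav)), , drop = FALSE]
  method <- if (identical(distance, "jaccard")) "binary" else distance
  d <- dist(pav, method = method)
  if (all(d == 0)) warning("all samples identical; single cluster")
  tree <- hclust(d, method = linkage)
  labels <- if (!is.null(k)) cutree(tree, k = k)
  list(tree = tree, labels = labels, dist = d)
}

#' PCA of a genotype dosage matrix
#'
#' Missing dosages are mean-imputed per marker; zero-variance markers are
#' dropped (reported via message); columns are centred and scaled to unit
#' variance before the decomposition.
#'
#' @param dosages Samples x markers numeric matrix.
#' @param k Number of components to return.
#' @return List with `scores` (samples x k), `loadings`, `explained`
#'   (variance per returned component), `explained_frac` and
#'   `n_markers` (markers retained).
#' @export
pca_dosages <- function(dosages, k = 10L) {
  stopifnot(nrow(dosages) >= 2L)
  for (j in seq_len(ncol(dosages))) {
    miss <- is.na(dosages[, j])
    if (any(miss)) dosages[miss, j] <- mean(dosages[, j], na.rm = TRUE)
  }
  v <- apply(dosages, 2, var)
  if (any(v == 0 | is.na(v))) {
    message(sum(v == 0 | is.na(v)), " zero-variance marker(s) dropped before PCA")
    dosages <- dosages[, v > 0 & !is.na(v), drop = FALSE]
  }
  if (!ncol(dosages)) stop("no polymorphic markers for PCA")
  pc <- prcomp(dosages, center = TRUE, scale. = TRUE)
  k <- min(k, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = pc$sdev^2,
       explained_frac = pc$sdev^2 / sum(pc$sdev^2),
       n_markers = ncol(dosages))
}

#' Adjusted Rand index between two labelings
#'
#' Agreement between inferred clusters and (e.g.) breed labels; 1 means the
#' partitions coincide up to label permutation.
#'
#' @param a,b Two label vectors over the same samples.
#' @return Adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
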