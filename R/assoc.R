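# Weighted mixed-linear-model association machinery: VanRaden GRM, REML
# variance components for the null model y = 1*mu + u + e with
# u ~ N(0, G sigma_u^2) and e ~ N(0, D sigma_e^2) (D diagonal, inverse
# per-animal accuracy weights), the per-marker scan with variance
# components held fixed, Bonferroni thresholds, trait transforms, and the
# iterative LD-window QTL-grouping procedure.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p_j (1 - p_j))` with `Z` the dosage matrix centred at
#' twice the observed allele frequencies. Missing dosages are mean-imputed
#' per marker; monomorphic markers are dropped.
#'
#' @param dosages Samples x markers matrix of 0/1/2 dosages.
#' @return Symmetric n x n matrix; for Hardy-Weinberg data its diagonal
#'   averages about 1.
#' @export
compute_grm <- function(dosages) {
  for (j in seq_len(ncol(dosages))) {
    miss <- is.na(dosages[, j])
    if (any(miss)) dosages[miss, j] <- mean(dosages[, j], na.rm = TRUE)
  }
  p <- colMeans(dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers monomorphic; GRM undefined")
  dosages <- dosages[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(dosages, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  (G + t(G)) / 2
}

.whiten <- function(y, G, weights) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  sw <- sqrt(weights)                      # D = diag(1/w); D^{-1/2} = diag(sqrt(w))
  Gs <- sweep(sweep(G, 1, sw, `*`), 2, sw, `*`)
  eig <- eigen(Gs, symmetric = TRUE)
  S <- pmax(eig$values, 0)
  U <- eig$vectors
  list(S = S, U = U, sw = sw, weights = weights,
       y = as.numeric(crossprod(U, sw * y)),
       x0 = as.numeric(crossprod(U, sw)))
}

.reml_ll <- function(lambda, wh) {
  d <- lambda * wh$S + 1
  a <- sum(wh$x0^2 / d)
  mu <- sum(wh$x0 * wh$y / d) / a
  rss <- sum((wh$y - mu * wh$x0)^2 / d)
  n <- length(wh$y)
  s2 <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(d)) + log(a))
  list(ll = ll, mu = mu, sigma_e2 = s2)
}

#' Restricted-likelihood profile of the null mixed model
#'
#' REML log-likelihood of `y = 1*mu + u + e` as a function of the variance
#' ratio `lambda = sigma_u^2 / sigma_e^2`, evaluated through the
#' eigendecomposition of the weight-whitened relationship matrix. Exposed
#' for grid checks of the optimiser.
#'
#' @param y Phenotype vector.
#' @param G Relationship matrix.
#' @param lambda Vector of variance ratios.
#' @param weights Per-animal accuracy weights `w_i` (residual variance
#'   `sigma_e^2 / w_i`); default all 1.
#' @return Numeric vector of REML log-likelihoods.
#' @export
reml_profile_loglik <- function(y, G, lambda, weights = NULL) {
  wh <- .whiten(y, G, weights)
  vapply(lambda, function(l) .reml_ll(l, wh)$ll, 0)
}

#' Fit the null mixed model by REML
#'
#' One-dimensional REML over `log(lambda)` after whitening by `D^{-1/2}`
#' and eigendecomposition of `D^{-1/2} G D^{-1/2}`; estimates at the search
#' boundary (`lambda -> 0` or very large) are flagged, as is the
#' unidentifiable `G = I` collapse where only `sigma_u^2 + sigma_e^2` is
#' determined.
#'
#' @inheritParams reml_profile_loglik
#' @return An object of class `mlm_null`: `mu`, `sigma_u2`, `sigma_e2`,
#'   `lambda`, `h2` (`sigma_u2 / (sigma_u2 + sigma_e2)`), `loglik`,
#'   `boundary` flag, and the cached whitening used by [mlma_scan].
#' @export
fit_null_reml <- function(y, G, weights = NULL) {
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations for the null fit")
  stopifnot(nrow(G) == n, ncol(G) == n)
  wh <- .whiten(y, G, weights)
  f <- function(loglam) .reml_ll(exp(loglam), wh)$ll
  lo <- -12; hi <- 12
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- exp(opt$maximum)
  fit <- .reml_ll(lambda, wh)
  boundary <- opt$maximum < lo + 0.05 || opt$maximum > hi - 0.05
  if (sum(abs(wh$S - mean(wh$S))) / n < 1e-10) boundary <- TRUE  # G ~ c*I
  sigma_u2 <- lambda * fit$sigma_e2
  resid_var <- fit$sigma_e2 * mean(1 / wh$weights)   # phenotype-scale residual
  out <- list(mu = fit$mu, sigma_u2 = sigma_u2,
              sigma_e2 = fit$sigma_e2, lambda = lambda,
              h2 = sigma_u2 / (sigma_u2 + resid_var), loglik = fit$ll,
              boundary = boundary, whitening = wh, n = n)
  class(out) <- "mlm_null"
  out
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf(
    "null mixed model: mu=%.4g  sigma_u2=%.4g  sigma_e2=%.4g  h2=%.3f%s\n",
    x$mu, x$sigma_u2, x$sigma_e2, x$h2,
    if (x$boundary) "  [boundary/unidentifiable]" else ""))
  invisible(x)
}

#' Mixed-linear-model association scan
#'
#' Tests each marker's fixed additive effect in `y = 1*mu + x*beta + u + e`
#' with the variance components held fixed from the null fit. Each marker's
#' generalised-least-squares estimate and Wald chi-square (1 df) test are
#' solved through the precomputed eigendecomposition; no per-marker matrix
#' inversion. Monomorphic markers are reported with `p = 1` and flagged.
#'
#' @param y Phenotype vector.
#' @param X Samples x markers dosage matrix (0/1/2 copies of the tested
#'   allele; missing mean-imputed per marker).
#' @param G Relationship matrix (ignored when `null` is supplied).
#' @param null An `mlm_null` from [fit_null_reml]; if `NULL` it is fitted.
#' @param weights Per-animal accuracy weights (as in [fit_null_reml]).
#' @return `data.table` with `marker_id`, `beta`, `se`, `chisq`,
#'   `p_value`, `neg_log10_p`, `monomorphic`.
#' @export
mlma_scan <- function(y, X, G = NULL, null = NULL, weights = NULL) {
  if (is.null(null)) {
    if (is.null(G)) stop("either G or a fitted null model is required")
    null <- fit_null_reml(y, G, weights = weights)
  }
  wh <- null$whitening
  d <- null$lambda * wh$S + 1
  ids <- colnames(X) %||% sprintf("m%d", seq_len(ncol(X)))
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  mono <- apply(X, 2, function(x) var(x) == 0)
  Xw <- crossprod(wh$U, wh$sw * X)               # whitened markers
  x0 <- wh$x0; yw <- wh$y
  A11 <- sum(x0^2 / d)
  b1 <- sum(x0 * yw / d)
  A12 <- colSums(Xw * (x0 / d))
  A22 <- colSums(Xw^2 / d)
  b2 <- colSums(Xw * (yw / d))
  det <- A11 * A22 - A12^2
  degenerate <- mono | det <= 0 | !is.finite(det)
  det[degenerate] <- 1
  beta <- (A11 * b2 - A12 * b1) / det
  var_beta <- null$sigma_e2 * A11 / det
  se <- sqrt(var_beta)
  chisq <- beta^2 / var_beta
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  beta[degenerate] <- NA_real_; se[degenerate] <- NA_real_
  chisq[degenerate] <- 0; p[degenerate] <- 1
  mono <- degenerate
  data.table(marker_id = ids, beta = beta, se = se, chisq = chisq,
             p_value = p, neg_log10_p = -log10(p), monomorphic = mono)
}

#' Bonferroni significance threshold
#'
#' @param alpha Nominal significance level.
#' @param m Number of tests (>= 1).
#' @return List with `p_threshold = alpha / m` and `neg_log10 =
#'   -log10(alpha / m)`.
#' @export
bonferroni <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  thr <- alpha / m
  list(p_threshold = thr, neg_log10 = -log10(thr))
}

#' Somatic cell score transform
#'
#' `SCS = 3 + log2(SCC / 100,000)` for somatic cell counts in cells/mL.
#'
#' @param scc Somatic cell count (> 0).
#' @return SCS value(s).
#' @export
scs_transform <- function(scc) {
  if (any(scc <= 0)) stop("SCC must be positive")
  3 + log2(scc / 1e5)
}

#' Group significant markers into QTL regions by LD windows
#'
#' Iterative clumping: the most significant unassigned marker becomes a
#' peak; every unassigned significant marker on the same chromosome within
#' the window around the peak whose squared Pearson correlation of dosages
#' with the peak exceeds `r2_threshold` joins its region; repeat until all
#' significant markers are assigned. Peak ties break by smaller p-value
#' then smaller position.
#'
#' @param results Scan results (`data.table` from [mlma_scan]) joined with
#'   genomic positions: needs `marker_id`, `chrom`, `pos`, `p_value`,
#'   `neg_log10_p`.
#' @param dosages Samples x markers dosage matrix covering the significant
#'   markers (for the r-squared computation).
#' @param threshold_neglogp Significance threshold on the -log10(p) scale.
#' @param window_bp Total window size centred on the peak (default 10 Mb).
#' @param r2_threshold LD threshold (r-squared, strict `>`).
#' @return `data.table` with one row per region: `region`, `chrom`,
#'   `peak_marker`, `peak_neg_log10_p`, `n_markers`, `start`, `end`, and
#'   the member ids in list column `members`.
#' @export
group_qtl <- function(results, dosages, threshold_neglogp,
                      window_bp = 1e7, r2_threshold = 0.7) {
  res <- as.data.table(results)
  stopifnot(all(c("marker_id", "chrom", "pos", "neg_log10_p") %in% names(res)))
  sig <- res[neg_log10_p >= threshold_neglogp]
  if (!nrow(sig))
    return(data.table(region = integer(), chrom = character(),
                      peak_marker = character(), peak_neg_log10_p = numeric(),
                      n_markers = integer(), start = integer(), end = integer(),
                      members = list()))
  missing <- setdiff(sig$marker_id, colnames(dosages))
  if (length(missing))
    stop("no dosages for significant markers: ", paste(head(missing, 5), collapse = ", "))
  sig[, assigned := FALSE]
  regions <- list()
  while (any(!sig$assigned)) {
    open <- sig[assigned == FALSE]
    setorder(open, -neg_log10_p, pos)
    peak <- open[1L]
    cand <- open[chrom == peak$chrom &
                   abs(pos - peak$pos) <= window_bp / 2]
    r2 <- suppressWarnings(
      cor(dosages[, cand$marker_id, drop = FALSE],
          dosages[, peak$marker_id],
          use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    member_ids <- cand$marker_id[r2 > r2_threshold | cand$marker_id == peak$marker_id]
    sig[marker_id %in% member_ids, assigned := TRUE]
    mem <- sig[marker_id %in% member_ids]
    regions[[length(regions) + 1L]] <- data.table(
      region = length(regions) + 1L, chrom = peak$chrom,
      peak_marker = peak$marker_id, peak_neg_log10_p = peak$neg_log10_p,
      n_markers = length(member_ids),
      start = min(mem$pos), end = max(mem$pos),
      members = list(member_ids))
  }
  rbindlist(regions)
}

utils::globalVariables(c("assigned"))
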