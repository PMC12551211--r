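# Mixed-model test utilities: an explicit-inverse GLS oracle and a
# structured-genotype simulator (Balding-Nichols groups) independent of the
# package's own generator.

gls_scan_explicit <- function(y, X, G, sigma_u2, sigma_e2, weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  V <- sigma_u2 * G + sigma_e2 * diag(1 / weights)
  Vi <- solve(V)
  t(vapply(seq_len(ncol(X)), function(j) {
    Xd <- cbind(1, X[, j])
    A <- solve(t(Xd) %*% Vi %*% Xd)
    b <- A %*% t(Xd) %*% Vi %*% y
    c(beta = b[2], se = sqrt(A[2, 2]))
  }, c(beta = 0, se = 0)))
}

# Half-sib family structure (the typical progeny-tested bull design):
# offspring draw one gamete from their sire and one from the population.
# The resulting relatedness makes variance components well identified.
sim_halfsib <- function(n, m, seed, n_sires = 25) {
  set.seed(seed)
  p <- stats::runif(m, 0.1, 0.9)
  sires <- matrix(stats::rbinom(n_sires * m, 2, rep(p, each = n_sires)),
                  n_sires, m)
  fam <- rep(seq_len(n_sires), length.out = n)
  g_sire <- matrix(stats::rbinom(n * m, 1, sires[fam, ] / 2), n, m)
  g_pop <- matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m)
  out <- g_sire + g_pop
  dimnames(out) <- list(sprintf("A%04d", 1:n), sprintf("m%04d", 1:m))
  out
}

sim_structured <- function(n, m, seed, n_groups = 4, fst = 0.1) {
  set.seed(seed)
  grp <- rep(seq_len(n_groups), length.out = n)
  p0 <- stats::runif(m, 0.1, 0.9)
  f <- vapply(p0, function(p)
    stats::rbeta(n_groups, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst),
    numeric(n_groups))
  matrix(stats::rbinom(n * m, 2, t(f[grp, ])), n, m, byrow = TRUE,
         dimnames = list(sprintf("A%04d", 1:n), sprintf("m%04d", 1:m)))
}
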