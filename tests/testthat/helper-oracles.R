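# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle recomputes a quantity by direct definition, never through
# the code path it checks.

# small FeatureTable from a plain matrix, auto-naming dims
ft <- function(m, layer = "taxa", kind = "count") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  feature_table(m, layer, kind)
}

# dense-matrix restricted log-likelihood: log-det and solves on the full
# covariance, independent of the eigendecomposition-rotation path
reml_loglik_dense <- function(h2, y, Xmat, A) {
  n <- length(y); p <- ncol(Xmat)
  V <- h2 * A + (1 - h2) * diag(n)
  Vi <- solve(V)
  XtViX <- t(Xmat) %*% Vi %*% Xmat
  beta <- solve(XtViX, t(Xmat) %*% Vi %*% y)
  r <- y - Xmat %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
            determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(XtViX, logarithm = TRUE)$modulus[1])
}

# grid-search REML: argmax of the dense restricted likelihood over an
# equispaced h2 grid
reml_grid_oracle <- function(y, Xmat, A, n_grid = 2000) {
  grid <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  ll <- vapply(grid, reml_loglik_dense, numeric(1), y = y, Xmat = Xmat, A = A)
  list(h2 = grid[which.max(ll)], loglik = max(ll), spacing = diff(grid[1:2]))
}

# boundary-mixture reference: p = 0.5 P(chi2_1 >= stat), 1 at stat = 0
lrt_pvalue_ref <- function(stat) {
  if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
}

# Benjamini-Hochberg by literal tail-min definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ranked <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  q[o] <- qs
  q
}

# exact two-sided Wilcoxon p by enumeration of all group assignments
wilcox_brute <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  combs <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# PERMANOVA pseudo-F by direct definition (explicit hat-matrix products)
permanova_f_brute <- function(D, z) {
  n <- nrow(D)
  G <- {
    A <- -0.5 * D^2
    J <- diag(n) - matrix(1 / n, n, n)
    J %*% A %*% J
  }
  X <- cbind(1, z)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  num <- sum(diag(H %*% G %*% H)) / 1
  den <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H))) / (n - 2)
  num / den
}

# full-enumeration PERMANOVA p at small n (includes the identity ordering)
permanova_p_enum <- function(D, z) {
  perms <- perms_of(length(z))
  f_obs <- permanova_f_brute(D, z)
  fs <- apply(perms, 1, function(ix) permanova_f_brute(D, z[ix]))
  mean(fs >= f_obs - 1e-12)
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# Bray-Curtis by the stated formula, double loop
bray_brute <- function(v) {
  n <- nrow(v)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    tot <- sum(v[i, ] + v[j, ])
    d[i, j] <- if (tot == 0) 0 else sum(abs(v[i, ] - v[j, ])) / tot
  }
  d
}

# cohort + single standardized layer + phenotype with one planted fraction;
# returns pieces needed for a variance-component fit
make_single_layer_cohort <- function(seed, n, q, fraction,
                                     layer_kind = "function") {
  cohort <- generate_cohort(seed, n_animals = n, n_hh = floor(n / 2))
  lay <- generate_omics_layer(seed + 7919L, cohort, layer_kind, n_features = q)
  z <- suppressWarnings(zscore_standardize(lay))
  fr <- stats::setNames(fraction, "layer")
  ph <- generate_phenotype_from_layers(seed + 15817L, cohort,
                                       list(layer = z), true_fractions = fr)
  list(phenotype = ph, z = z, A = build_relationship_matrix(z))
}
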