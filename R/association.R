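#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties get average ranks); the
#' two-sided p-value uses `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. A perfectly monotone pair (`|rho| = 1`) gets the
#' smallest representable positive p and is flagged.
#'
#' @param x,y numeric vectors, length >= 4, finite.
#' @return list with `rho`, `p`, `n`, `exact_monotone`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    return(list(rho = sign(rho), p = .Machine$double.xmin, n = n,
                exact_monotone = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(rho = rho, p = p, n = n, exact_monotone = FALSE)
}

# vectorized spearman of each column of X against each column of Y:
# returns list(rho = qx x qy matrix, p = matrix)
spearman_matrix <- function(X, Y) {
  RX <- apply(X, 2, rank)
  RY <- apply(Y, 2, rank)
  n <- nrow(X)
  rho <- stats::cor(RX, RY)
  rho_c <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-15] <- .Machine$double.xmin
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen phenotype-associated metabotypes
#'
#' Spearman-correlates every metabolite with MPY and classifies each as
#' MPY-positive (`rho > 0`, `p < alpha`), MPY-negative (`rho < 0`,
#' `p < alpha`) or unassociated. The screen uses raw p-values, per the
#' two-stage design in which FDR control is applied later at the
#' microbiome-responsiveness stage. Constant metabolite columns are excluded
#' with a warning; missing peaks are excluded pairwise.
#'
#' @param metabolome a metabolome `FeatureTable` (any value kind; ranks are
#'   invariant to monotone transforms).
#' @param phenotype a `PhenotypeTable` with the same samples in the same
#'   order.
#' @param alpha screening significance level (default 0.05).
#' @return data.frame: `metabolite_id`, `rho`, `p_spearman`, `sign_class`.
#' @export
screen_metabotypes <- function(metabolome, phenotype, alpha = 0.05) {
  stopifnot(inherits(metabolome, "FeatureTable"))
  if (!identical(rownames(metabolome$values), phenotype$sample_id))
    stop("metabolome and phenotype must share sample order")
  v <- metabolome$values
  mpy <- phenotype$mpy
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    ok <- !is.na(x)
    if (sum(ok) < 4 || stats::sd(x[ok]) == 0) return(NULL)
    s <- spearman_cor(x[ok], mpy[ok])
    data.frame(metabolite_id = colnames(v)[j], rho = s$rho,
               p_spearman = s$p)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " constant or too-sparse metabolite(s) excluded")
  out <- do.call(rbind, res)
  out$sign_class <- ifelse(out$p_spearman >= alpha, "none",
                           ifelse(out$rho > 0, "MPY-positive", "MPY-negative"))
  out
}

#' PERMANOVA of a distance matrix on one continuous covariate
#'
#' Pseudo-F from the Gower-centered inner-product matrix
#' `G = -1/2 J D^2 J` and the hat matrix `H` of the design
#' `[1, covariate]`: `F = [tr(HGH)/m] / [tr((I-H)G(I-H))/(n-m-1)]` with
#' `m = 1`. The p-value permutes the covariate entries with the add-one
#' estimator `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d a `DistanceMatrix`.
#' @param covariate numeric vector of length n (e.g. one metabotype).
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed integer seed for the permutation stream.
#' @return list with `pseudo_F`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(d, covariate, n_perm = 999, seed = 1) {
  stopifnot(inherits(d, "DistanceMatrix"))
  D <- d$values
  n <- nrow(D)
  if (length(covariate) != n) stop("covariate length must match the distance matrix")
  if (anyNA(D) || anyNA(covariate)) stop("missing values are not allowed")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  if (n_perm < 99) stop("use at least 99 permutations")
  G <- gower_center(D)
  trG <- sum(diag(G))
  m <- 1
  f_of <- function(z) {
    # tr(HGH) = tr(GH) = sum(G * H) for idempotent symmetric H
    X <- cbind(1, z)
    H <- X %*% solve(crossprod(X), t(X))
    trGH <- sum(G * H)
    (trGH / m) / ((trG - trGH) / (n - m - 1))
  }
  f_obs <- f_of(covariate)
  withr_seed(seed)
  exceed <- 0L
  tol <- 1e-12 * max(1, abs(f_obs))  # count exact ties despite float noise
  for (i in seq_len(n_perm))
    if (f_of(sample(covariate)) >= f_obs - tol) exceed <- exceed + 1L
  list(pseudo_F = f_obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Full metabotype analysis: screen, PERMANOVA, FDR
#'
#' Two-stage procedure: (1) Spearman screen of every metabolite against MPY
#' at raw `alpha`; (2) for each screened metabotype, PERMANOVA of the
#' microbial Bray-Curtis distance on the metabotype values, with BH FDR over
#' the screened set; metabotypes with `q < fdr` are flagged
#' microbiome-responsive.
#'
#' @inheritParams screen_metabotypes
#' @param taxa_distance a `DistanceMatrix` of the (filtered) taxa layer.
#' @param fdr FDR threshold for microbiome responsiveness (default 0.05).
#' @param n_perm,seed passed to [permanova()] (per-metabotype seeds are
#'   derived as `seed + index`).
#' @return data.frame: screening columns plus `permanova_F`, `p_permanova`,
#'   `q_permanova`, `microbiome_responsive` (`NA` for unscreened
#'   metabolites).
#' @export
metabotype_analysis <- function(metabolome, phenotype, taxa_distance,
                                alpha = 0.05, fdr = 0.05,
                                n_perm = 999, seed = 1) {
  scr <- screen_metabotypes(metabolome, phenotype, alpha = alpha)
  scr$permanova_F <- NA_real_
  scr$p_permanova <- NA_real_
  scr$q_permanova <- NA_real_
  scr$microbiome_responsive <- FALSE
  hits <- which(scr$sign_class != "none")
  if (length(hits)) {
    for (k in seq_along(hits)) {
      i <- hits[k]
      x <- metabolome$values[, scr$metabolite_id[i]]
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      pr <- permanova(taxa_distance, x, n_perm = n_perm, seed = seed + k)
      scr$permanova_F[i] <- pr$pseudo_F
      scr$p_permanova[i] <- pr$p
    }
    scr$q_permanova[hits] <- bh_fdr(scr$p_permanova[hits])
    scr$microbiome_responsive[hits] <- scr$q_permanova[hits] < fdr
  }
  scr
}

#' Thresholded cross-table Spearman correlation network
#'
#' Correlates every feature of `table_a` with every feature of `table_b` and
#' keeps edges with `|rho| > r_threshold` and `p < alpha`. Edges are ordered
#' by (a-feature, b-feature) id.
#'
#' @param table_a,table_b `FeatureTable`s sharing the same samples in the
#'   same order (missing entries are imputed to the feature mean for
#'   ranking).
#' @param r_threshold minimum absolute Spearman rho (default 0.5).
#' @param alpha maximum p-value (default 0.05).
#' @return data.frame: `node_a`, `node_b`, `rho`, `p`.
#' @export
build_correlation_network <- function(table_a, table_b,
                                      r_threshold = 0.5, alpha = 0.05) {
  stopifnot(inherits(table_a, "FeatureTable"), inherits(table_b, "FeatureTable"))
  if (!identical(rownames(table_a$values), rownames(table_b$values)))
    stop("tables must share samples in the same order")
  impute <- function(v) {
    for (j in seq_len(ncol(v))) {
      nas <- is.na(v[, j])
      if (any(nas)) v[nas, j] <- mean(v[!nas, j])
    }
    v
  }
  A <- impute(table_a$values)
  B <- impute(table_b$values)
  keepvar <- function(v) apply(v, 2, stats::sd) > 0
  A <- A[, keepvar(A), drop = FALSE]
  B <- B[, keepvar(B), drop = FALSE]
  sm <- spearman_matrix(A, B)
  keep <- which(abs(sm$rho) > r_threshold & sm$p < alpha, arr.ind = TRUE)
  out <- data.frame(node_a = colnames(A)[keep[, 1]],
                    node_b = colnames(B)[keep[, 2]],
                    rho = sm$rho[keep], p = sm$p[keep])
  out[order(out$node_a, out$node_b), , drop = FALSE]
}
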