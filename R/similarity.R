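#' Omics relationship matrix
#'
#' Builds the n x n sample-similarity matrix `A = Z Z' / q` from a
#' column-standardized omics layer with `q` features (the covariance kernel
#' of the layer's random effect in the mixed model; the microbial **M**,
#' functional **K**, rumen-metabolome **R** and serum-metabolome **S**
#' matrices are all built this way). Division by the feature count makes the
#' kernel scale-free; with fully standardized columns (sample sd) the trace
#' is exactly `n - 1`.
#'
#' @param z a `FeatureTable` with `value_kind = "zscore"`.
#' @return an object of class `RelationshipMatrix`: list with `values`
#'   (n x n, dimnames = sample ids), `source_layer`, `n_features_used`.
#' @export
build_relationship_matrix <- function(z) {
  stopifnot(inherits(z, "FeatureTable"))
  if (z$value_kind != "zscore")
    stop("relationship matrices are built from zscore-standardized tables")
  q <- ncol(z$values)
  if (q < 1) stop("no features left to build the relationship matrix")
  A <- tcrossprod(z$values) / q
  structure(list(values = A, source_layer = z$layer_kind,
                 n_features_used = q),
            class = "RelationshipMatrix")
}

#' @export
print.RelationshipMatrix <- function(x, ...) {
  cat(sprintf("<RelationshipMatrix> %s: %d x %d from %d features\n",
              x$source_layer, nrow(x$values), ncol(x$values),
              x$n_features_used))
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum|x_i - x_j| / sum(x_i + x_j)` over features, computed with
#' \code{vegan::vegdist}. A pair of samples with all-zero combined abundance
#' has undefined dissimilarity; it is set to 0 with a warning.
#'
#' @param t a `FeatureTable` with non-negative values and no missing entries
#'   (`relative`, `count` or `cpm`).
#' @return an object of class `DistanceMatrix`: list with `values` (full
#'   symmetric n x n matrix, zero diagonal, entries in \[0, 1\]).
#' @export
bray_curtis <- function(t) {
  stopifnot(inherits(t, "FeatureTable"))
  v <- t$values
  if (anyNA(v)) stop("missing values are not allowed in Bray-Curtis input")
  if (any(v < 0)) stop("negative entries are not allowed")
  # vegdist warns about empty rows / NaN pairs itself; the all-zero-pair
  # convention below replaces those warnings with a single defined one
  d <- as.matrix(suppressWarnings(vegan::vegdist(v, method = "bray")))
  if (anyNA(d)) {
    warning("pair(s) with all-zero combined abundance; dissimilarity set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  structure(list(values = d), class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("<DistanceMatrix> %d samples\n", nrow(x$values)))
  invisible(x)
}

#' Principal-coordinates analysis (classical MDS)
#'
#' Gower-centers `-D^2/2`, eigendecomposes, and returns the top-`k`
#' coordinate axes. Negative eigenvalues (non-Euclidean input) are clamped
#' to 0 and excluded from the proportion-explained denominator.
#'
#' @param d a `DistanceMatrix`.
#' @param k number of axes (default 2; must be <= n - 1).
#' @return list with `coordinates` (n x k), `eigenvalues` (length n - 1,
#'   clamped at 0) and `proportion_explained` (per returned axis).
#' @export
pcoa <- function(d, k = 2) {
  stopifnot(inherits(d, "DistanceMatrix"))
  n <- nrow(d$values)
  if (k > n - 1) stop("k must be <= n - 1")
  # cmdscale warns when fewer than k eigenvalues are positive; that case is
  # part of the clamp-to-zero convention here, so the warning is not an issue
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d$values), k = k,
                                          eig = TRUE))
  eig <- pmax(fit$eig, 0)[seq_len(n - 1)]
  coords <- fit$points
  if (is.null(dim(coords)) || ncol(coords) < k) {
    # cmdscale drops trailing zero-eigenvalue axes; pad with zeros
    pad <- matrix(0, n, k, dimnames = list(rownames(d$values), NULL))
    if (!is.null(coords) && length(coords)) pad[, seq_len(ncol(coords))] <- coords
    coords <- pad
  }
  denom <- sum(eig)
  prop <- if (denom > 0) eig[seq_len(k)] / denom else rep(0, k)
  rownames(coords) <- rownames(d$values)
  list(coordinates = coords, eigenvalues = eig, proportion_explained = prop)
}

#' Write / read a square matrix as TSV with sample ids
#'
#' @param m a `RelationshipMatrix`, `DistanceMatrix` or plain square matrix.
#' @param path file path.
#' @export
write_square_matrix <- function(m, path) {
  v <- if (is.list(m)) m$values else m
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
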