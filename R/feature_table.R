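#' Sample-by-feature table for one omics layer
#'
#' The basic container of the package: an `n_samples x n_features` numeric
#' matrix with declared layer and value semantics. Rows are samples (animals),
#' columns are features (microbial species, KEGG orthologs, metabolites).
#' `NaN`/`NA` entries are allowed only for metabolome layers, where they mean
#' "peak not detected in this sample".
#'
#' @param values numeric matrix, samples in rows, with row and column names.
#' @param layer_kind one of `"taxa"`, `"function"`, `"rumen_metabolome"`,
#'   `"serum_metabolome"`.
#' @param value_kind one of `"count"`, `"relative"`, `"cpm"`, `"intensity"`,
#'   `"zscore"`. `relative` rows must sum to 1, `cpm` rows to 1e6, `zscore`
#'   columns must have mean 0 and unit sample sd.
#' @param feature_meta optional data.frame of per-feature attributes keyed by
#'   a `feature_id` column (e.g. spectral `similarity` score and `identified`
#'   flag for metabolite peaks, `lineage` for taxa).
#' @return an object of class `FeatureTable`.
#' @export
feature_table <- function(values, layer_kind, value_kind, feature_meta = NULL) {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample (row) and feature (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids")
  if (anyNA(values) && !is_metabolome(layer_kind))
    stop("missing values are only allowed in metabolome layers")
  if (value_kind != "zscore" && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed for value_kind ", value_kind)
  x <- structure(list(values = values, layer_kind = layer_kind,
                      value_kind = value_kind, feature_meta = feature_meta),
                 class = "FeatureTable")
  validate_feature_table(x)
  x
}

# column subset of a table: a filtered relative/cpm table is a
# sub-composition whose rows no longer close to 1 / 1e6, so the closure
# invariants apply only at construction from full data, not after retention
# filters
feature_table_subset <- function(t, keep) {
  structure(list(values = t$values[, keep, drop = FALSE],
                 layer_kind = t$layer_kind, value_kind = t$value_kind,
                 feature_meta = t$feature_meta),
            class = "FeatureTable")
}

LAYER_KINDS <- c("taxa", "function", "rumen_metabolome", "serum_metabolome")
VALUE_KINDS <- c("count", "relative", "cpm", "intensity", "zscore")

is_metabolome <- function(layer_kind)
  layer_kind %in% c("rumen_metabolome", "serum_metabolome")

validate_feature_table <- function(x) {
  v <- x$values
  if (x$value_kind == "relative") {
    rs <- rowSums(v, na.rm = TRUE)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-abundance rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  } else if (x$value_kind == "cpm") {
    rs <- rowSums(v, na.rm = TRUE)
    if (any(abs(rs - 1e6) > 1e-3))
      stop("cpm rows must sum to 1e6")
  } else if (x$value_kind == "zscore") {
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-9))
      stop("zscore columns must have mean 0 and unit sample sd")
  }
  if (!is.null(x$feature_meta)) {
    if (!"feature_id" %in% names(x$feature_meta))
      stop("feature_meta must have a feature_id column")
    if (!all(colnames(v) %in% x$feature_meta$feature_id))
      stop("feature_meta must cover every feature")
  }
  invisible(x)
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("<FeatureTable> %s [%s]: %d samples x %d features\n",
              x$layer_kind, x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `FeatureTable` or `PhenotypeTable`.
#' @export
sample_ids <- function(x) {
  if (inherits(x, "FeatureTable")) rownames(x$values) else x$sample_id
}

#' @rdname feature_table
#' @export
feature_ids <- function(x) colnames(x$values)

#' Per-animal phenotype and covariates
#'
#' Validated data.frame with one row per animal: milk protein yield
#' (`mpy`, kg/day), `parity` (lactation number), `dim` (days in milk) and
#' optionally `milk_yield` (kg/day), `protein_content` (fraction) and the
#' extreme-group label `group` (`"HH"`/`"LL"`). When both `milk_yield` and
#' `protein_content` are present, `mpy` must equal their product.
#'
#' @param df data.frame with at least `sample_id`, `mpy`, `parity`, `dim`.
#' @return the validated data.frame with class `PhenotypeTable` prepended.
#' @export
phenotype_table <- function(df) {
  req <- c("sample_id", "mpy", "parity", "dim")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (any(df$mpy <= 0)) stop("mpy must be positive")
  if (any(df$dim <= 0)) stop("dim must be positive")
  if (any(df$parity < 1)) stop("parity must be >= 1")
  if (all(c("milk_yield", "protein_content") %in% names(df))) {
    if (any(abs(df$mpy - df$milk_yield * df$protein_content) > 1e-6))
      stop("mpy must equal milk_yield * protein_content")
  }
  class(df) <- c("PhenotypeTable", "data.frame")
  df
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read a delimited feature table
#'
#' Reads a TSV/CSV (auto-detected from the header line) with one id column
#' and one header row into a [feature_table()]. Empty cells become `NaN` for
#' metabolome layers and are an error elsewhere; any other non-numeric cell
#' is an error.
#'
#' @param path file path.
#' @inheritParams feature_table
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`;
#'   the returned table always has samples in rows.
#' @param feature_meta optional data.frame (or path to a delimited sidecar
#'   with a `feature_id` column) of per-feature attributes.
#' @return a `FeatureTable`.
#' @export
read_feature_table <- function(path, layer_kind, value_kind,
                               orientation = c("samples_in_rows", "features_in_rows"),
                               feature_meta = NULL) {
  orientation <- match.arg(orientation)
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  m <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    empty <- !nzchar(cell) | cell %in% c("NA", "NaN")  # absent peak markers
    num <- suppressWarnings(as.numeric(cell))
    bad <- is.na(num) & !empty
    if (any(bad))
      stop("non-numeric cell(s) in column '", colnames(raw)[j], "': ",
           cell[which(bad)[1]])
    if (any(empty) && !is_metabolome(layer_kind))
      stop("empty cells are only allowed in metabolome layers")
    num[empty] <- NaN
    m[, j] <- num
  }
  if (orientation == "features_in_rows") m <- t(m)
  if (is.character(feature_meta))
    feature_meta <- utils::read.table(feature_meta, header = TRUE,
                                      sep = detect_sep(feature_meta),
                                      check.names = FALSE)
  feature_table(m, layer_kind, value_kind, feature_meta)
}

#' Write a feature table as TSV
#'
#' @param t a `FeatureTable`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_feature_table <- function(t, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(t$values), t$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")  # absent peaks round-trip as empty cells
  invisible(path)
}

#' Read a phenotype table (samples in rows)
#'
#' @param path delimited file with a header; columns as in [phenotype_table()].
#' @return a `PhenotypeTable`.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          check.names = FALSE)
  phenotype_table(df)
}

#' Convert counts to relative abundances
#'
#' Each row is closed to sum 1 (total-sum scaling). All row sums must be
#' positive.
#'
#' @param t a `FeatureTable` with `value_kind = "count"`.
#' @return a `FeatureTable` with `value_kind = "relative"`.
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "FeatureTable"))
  rs <- rowSums(t$values)
  if (any(rs <= 0)) stop("zero row sum: cannot close to relative abundance")
  feature_table(t$values / rs, t$layer_kind, "relative", t$feature_meta)
}

#' Convert counts to counts-per-million
#'
#' @inheritParams to_relative_abundance
#' @return a `FeatureTable` with `value_kind = "cpm"` (rows sum to 1e6).
#' @export
to_cpm <- function(t) {
  stopifnot(inherits(t, "FeatureTable"))
  rs <- rowSums(t$values)
  if (any(rs <= 0)) stop("zero row sum: cannot scale to cpm")
  feature_table(t$values * 1e6 / rs, t$layer_kind, "cpm", t$feature_meta)
}

#' Prevalence-abundance feature retention
#'
#' Keeps a feature iff, in EVERY group, the fraction of samples whose value is
#' strictly greater than `threshold` is at least `min_fraction`. This is the
#' retention rule "relative abundance > 0.1% in at least 50% of cows within
#' each group" (taxa, `threshold = 0.001`) and "cpm > 5 in at least 50% of
#' animals within each group" (functions, `threshold = 5`).
#'
#' @param t a `FeatureTable`.
#' @param groups named character vector mapping every sample id to a group.
#' @param threshold abundance cutoff (strict `>`).
#' @param min_fraction minimum within-group fraction of samples, in (0, 1].
#' @return the filtered `FeatureTable` (feature order preserved).
#' @export
filter_prevalent_features <- function(t, groups, threshold, min_fraction = 0.5) {
  stopifnot(inherits(t, "FeatureTable"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  sid <- rownames(t$values)
  if (!all(sid %in% names(groups)))
    stop("every sample must be assigned to a group")
  g <- factor(groups[sid])
  if (any(table(g) == 0)) stop("empty group")
  keep <- rep(TRUE, ncol(t$values))
  for (lev in levels(g)) {
    sub <- t$values[g == lev, , drop = FALSE]
    frac <- colMeans(!is.na(sub) & sub > threshold)  # missing peak = below cutoff
    keep <- keep & (frac >= min_fraction)
  }
  feature_table_subset(t, keep)
}

#' Metabolite peak quality filter
#'
#' Removes peaks failing any of: detected (non-missing) in at least
#' `min_presence` of samples; relative standard deviation
#' (`sd/mean * 100`, sample sd) at most `max_rsd`; spectral similarity at
#' least `min_similarity`; identified. Requires `feature_meta` columns
#' `similarity` and `identified`.
#'
#' @param t a metabolome `FeatureTable` with `value_kind = "intensity"`.
#' @param qc_samples optional sample ids over which the RSD is computed
#'   (default: all samples with a detected peak).
#' @param min_presence minimum detection fraction (default 0.5).
#' @param max_rsd maximum RSD in percent (default 30).
#' @param min_similarity minimum spectral similarity score (default 200).
#' @return the filtered `FeatureTable`.
#' @export
filter_metabolite_peaks <- function(t, qc_samples = NULL, min_presence = 0.5,
                                    max_rsd = 30, min_similarity = 200) {
  stopifnot(inherits(t, "FeatureTable"))
  meta <- t$feature_meta
  if (is.null(meta) || !all(c("similarity", "identified") %in% names(meta)))
    stop("feature_meta with `similarity` and `identified` columns is required")
  meta <- meta[match(colnames(t$values), meta$feature_id), ]
  v <- t$values
  pres <- colMeans(!is.na(v))
  rsd_rows <- if (is.null(qc_samples)) v else v[qc_samples, , drop = FALSE]
  rsd <- vapply(seq_len(ncol(rsd_rows)), function(j) {
    x <- rsd_rows[, j]
    x <- x[!is.na(x)]
    if (length(x) < 2) return(Inf)
    m <- mean(x)
    if (m == 0) {
      warning("zero mean intensity for feature ", colnames(v)[j],
              "; treating as failing the RSD filter")
      return(Inf)
    }
    stats::sd(x) / m * 100
  }, numeric(1))
  keep <- pres >= min_presence & rsd <= max_rsd &
    meta$similarity >= min_similarity & as.logical(meta$identified)
  feature_table_subset(t, keep)
}

#' Column-standardize a feature table
#'
#' Missing entries are imputed to the column mean (thus becoming 0 after
#' centering), then each column is centered and scaled by its sample standard
#' deviation (n-1 denominator). Zero-variance columns are dropped with a
#' warning.
#'
#' @param t a `FeatureTable` with at least 2 samples.
#' @return a `FeatureTable` with `value_kind = "zscore"`.
#' @export
zscore_standardize <- function(t) {
  stopifnot(inherits(t, "FeatureTable"))
  v <- t$values
  if (nrow(v) < 2) stop("need at least 2 samples to standardize")
  for (j in seq_len(ncol(v))) {
    nas <- is.na(v[, j])
    if (any(nas)) v[nas, j] <- mean(v[!nas, j])
  }
  sdv <- apply(v, 2, stats::sd)
  drop <- sdv == 0 | is.na(sdv)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance feature(s): ",
            paste(utils::head(colnames(v)[drop], 5), collapse = ", "))
    v <- v[, !drop, drop = FALSE]
    sdv <- sdv[!drop]
  }
  if (ncol(v) == 0) stop("no features left after dropping zero-variance columns")
  v <- scale(v, center = TRUE, scale = sdv)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  feature_table(v, t$layer_kind, "zscore", t$feature_meta)
}

#' Aggregate cpm features into modules by summation
#'
#' Sums cpm columns that share a module id (e.g. KEGG orthologs into KEGG
#' modules). Features absent from `mapping` are dropped.
#'
#' @param t a `FeatureTable` (typically `value_kind = "cpm"`).
#' @param mapping named character vector feature_id -> module id.
#' @return a plain numeric matrix, samples x modules.
#' @export
aggregate_by_module <- function(t, mapping) {
  stopifnot(inherits(t, "FeatureTable"))
  feats <- intersect(colnames(t$values), names(mapping))
  if (!length(feats)) stop("no features covered by the mapping")
  mods <- factor(mapping[feats])
  out <- sapply(levels(mods), function(m)
    rowSums(t$values[, feats[mods == m], drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(t$values),
                                       dimnames = list(rownames(t$values), levels(mods)))
  out
}
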