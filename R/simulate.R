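#' Synthetic multi-omics dairy cohort
#'
#' Generators that emulate the statistical structure the analysis assumes:
#' a small cohort of mid-lactation cows with parity and days-in-milk
#' covariates, a compositional taxa table dominated by one genus block, a
#' counts-per-million function table, log-normal metabolite intensity tables
#' with missing peaks, and a milk-protein-yield (MPY) phenotype assembled
#' additively from the standardized layers with user-specified true variance
#' fractions. A truth record accompanies every cohort so parameter-recovery
#' tests can compare estimates with what was planted.
#'
#' @name synthetic-cohort
NULL

#' Default per-layer variance fractions of MPY
#'
#' Taxa, functions, rumen metabolome, serum metabolome; they sum to ~0.96 so
#' a small residual share remains.
#' @export
default_true_fractions <- function() {
  c(taxa = 0.1781, `function` = 0.2156,
    rumen_metabolome = 0.2976, serum_metabolome = 0.2678)
}

#' Generate cohort covariates
#'
#' Parity and days-in-milk are uniform on their ranges; MPY is filled later
#' by [generate_phenotype_from_layers()], after which group labels are
#' assigned by ranking MPY (top `n_hh` animals -> HH, the rest -> LL),
#' mirroring extreme-group selection.
#'
#' @param seed integer seed.
#' @param n_animals cohort size (default 16).
#' @param n_hh number of high-MPY animals (default 7; the rest are LL).
#' @param parity_range inclusive integer range of parities.
#' @param dim_range inclusive integer range of days in milk (mid-lactation).
#' @return a `PhenotypeTable` with `mpy` set to a placeholder `NA`-free 1
#'   until the phenotype is generated (column `mpy_filled = FALSE`).
#' @export
generate_cohort <- function(seed, n_animals = 16, n_hh = 7,
                            parity_range = c(1L, 4L),
                            dim_range = c(60L, 180L)) {
  if (n_hh > n_animals) stop("n_hh must be <= n_animals")
  if (diff(range(parity_range)) < 0 || diff(range(dim_range)) < 0)
    stop("empty range")
  withr_seed(seed)
  df <- data.frame(
    sample_id = sprintf("cow%03d", seq_len(n_animals)),
    mpy = 1,  # placeholder until generate_phenotype_from_layers()
    parity = sample(seq(parity_range[1], parity_range[2]), n_animals,
                    replace = TRUE),
    dim = sample(seq(dim_range[1], dim_range[2]), n_animals, replace = TRUE)
  )
  out <- phenotype_table(df)
  attr(out, "n_hh") <- n_hh
  attr(out, "mpy_filled") <- FALSE
  out
}

# local seed helper: sets the RNG reproducibly without clobbering the caller's
# stream beyond this call chain (plain set.seed is fine for package internals,
# but keep one entry point so every generator uses the same RNG kind)
withr_seed <- function(seed) set.seed(as.integer(seed %% .Machine$integer.max),
                                      kind = "Mersenne-Twister")

#' Generate one synthetic omics layer
#'
#' Taxa layers are log-normal abundance profiles closed to relative form with
#' one dominant feature block whose mean share is configurable (emulating a
#' community dominated by a single genus); function layers are log-normal
#' count profiles scaled to counts-per-million; metabolome layers are
#' log-normal peak intensities with random missingness and a sidecar of
#' spectral similarity scores. Planted group effects multiply the named
#' features by `exp(lfc)` in HH animals (for taxa, before closure).
#'
#' @param seed integer seed.
#' @param cohort a `PhenotypeTable` from [generate_cohort()]; if groups are
#'   not assigned yet, the first `n_hh` animals stand in as the effect group.
#' @param layer_kind layer to generate.
#' @param n_features number of features (defaults per layer: 150 taxa,
#'   400 functions, 263 rumen and 177 serum metabolites).
#' @param effect_spec named numeric vector feature_id -> log-fold effect in
#'   HH animals (empty = null layer).
#' @param dominance_share target mean share of the dominant taxa block
#'   (taxa only; default 0.42).
#' @param n_dominant number of features in the dominant block (default 10).
#' @param sample_sd per-sample log-scale noise sd (default 0.35 for taxa and
#'   function layers; 0.25 for metabolomes, i.e. a ~25% coefficient of
#'   variation, typical of post-QC peak intensities).
#' @param missing_rate expected fraction of missing peaks (metabolomes only).
#' @return a `FeatureTable` of the appropriate `value_kind`.
#' @export
generate_omics_layer <- function(seed, cohort, layer_kind,
                                 n_features = NULL, effect_spec = numeric(),
                                 dominance_share = 0.42, n_dominant = 10,
                                 sample_sd = NULL, missing_rate = 0.05) {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  if (is.null(sample_sd))
    sample_sd <- if (is_metabolome(layer_kind)) 0.25 else 0.35
  if (is.null(n_features))
    n_features <- switch(layer_kind, taxa = 150, `function` = 400,
                         rumen_metabolome = 263, serum_metabolome = 177)
  withr_seed(seed)
  n <- nrow(cohort)
  ids <- cohort$sample_id
  feats <- sprintf("%s_%03d", switch(layer_kind, taxa = "sp",
                                     `function` = "ko",
                                     rumen_metabolome = "rmet",
                                     serum_metabolome = "smet"),
                   seq_len(n_features))
  if (length(effect_spec) && !all(names(effect_spec) %in% feats))
    stop("effect_spec names features that do not exist in the layer")
  # base (expected) log-profile shared by all samples
  base <- stats::rnorm(n_features, 0, 1.2)
  if (layer_kind == "taxa" && n_dominant > 0) {
    # rescale the dominant block so its share of the base profile hits target
    b <- exp(base)
    dom <- seq_len(min(n_dominant, n_features))
    s_dom <- sum(b[dom]); s_rest <- sum(b[-dom])
    b[dom] <- b[dom] * dominance_share * s_rest / ((1 - dominance_share) * s_dom)
    base <- log(b)
  }
  logv <- matrix(stats::rnorm(n * n_features, 0, sample_sd), n, n_features)
  logv <- sweep(logv, 2, base, `+`)
  if (length(effect_spec)) {
    hh <- effect_group(cohort)
    j <- match(names(effect_spec), feats)
    logv[hh, j] <- sweep(logv[hh, j, drop = FALSE], 2, effect_spec, `+`)
  }
  v <- exp(logv)
  dimnames(v) <- list(ids, feats)
  if (layer_kind == "taxa") {
    feature_table(v / rowSums(v), layer_kind, "relative")
  } else if (layer_kind == "function") {
    feature_table(v * 1e6 / rowSums(v), layer_kind, "cpm")
  } else {
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(n * n_features) < missing_rate, n, n_features)
      # keep every peak detectable somewhere
      miss[1, ] <- miss[1, ] & FALSE
      v[miss] <- NaN
    }
    meta <- data.frame(feature_id = feats,
                       similarity = round(stats::runif(n_features, 400, 950)),
                       identified = TRUE)
    feature_table(v, layer_kind, "intensity", feature_meta = meta)
  }
}

# rows receiving the planted HH effect: the labelled HH group when available,
# else the first n_hh animals (labels are assigned only after the phenotype)
effect_group <- function(cohort) {
  if (!is.null(cohort$group)) which(cohort$group == "HH")
  else seq_len(attr(cohort, "n_hh") %||% ceiling(nrow(cohort) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the MPY phenotype from standardized layers
#'
#' `mpy = mu + parity effect + dim * slope + sum_layer u_layer + e` with
#' `u_layer = Z w`, `w ~ N(0, sigma2_layer / q)` per column, so that
#' `Var(u_layer)` has the layer's relationship-matrix covariance
#' `sigma2_layer * ZZ'/q`. Layer variances are `true_fractions * total_var`
#' and the residual takes the remaining share. If any assembled MPY is
#' non-positive the whole vector is shifted up (variance unchanged). Group
#' labels are then assigned by MPY rank (top `n_hh` -> HH).
#'
#' @param seed integer seed.
#' @param cohort a `PhenotypeTable` from [generate_cohort()].
#' @param layers named list of `zscore` `FeatureTable`s (names are layer
#'   labels used in `true_fractions`).
#' @param true_fractions named vector of per-layer fractions of `total_var`,
#'   each in \[0, 1), summing to < 1; layers absent from the vector get 0.
#' @param total_var total random (layer + residual) variance, kg^2/day^2.
#' @param mu intercept, kg/day.
#' @param parity_effects numeric vector of per-parity additive effects
#'   (recycled over observed parities), kg/day.
#' @param dim_slope linear days-in-milk slope, kg/day per day.
#' @param scale_realized if `TRUE`, rescale each layer's aggregate effect so
#'   its realized sample variance equals `sigma2_layer` exactly (the usual
#'   convention in variance-component recovery simulations, where the planted
#'   signal is controlled rather than left to the luck of the effect draw);
#'   default `FALSE` draws `w` untouched, so the realized share fluctuates
#'   around the target with relative sd about `sqrt(2/q)`.
#' @return the cohort with `mpy` filled, `group` assigned, and a `truth`
#'   attribute (list: seed, fractions, variances, effects).
#' @export
generate_phenotype_from_layers <- function(seed, cohort, layers,
                                           true_fractions = default_true_fractions(),
                                           total_var = 1, mu = 1.2,
                                           parity_effects = c(0, 0.08, 0.12, 0.10),
                                           dim_slope = -0.002,
                                           scale_realized = FALSE) {
  if (sum(true_fractions) >= 1) stop("true variance fractions must sum to < 1")
  if (length(layers) && is.null(names(layers))) stop("layers must be named")
  for (l in layers) {
    stopifnot(inherits(l, "FeatureTable"))
    if (!identical(rownames(l$values), cohort$sample_id))
      stop("layer sample order must match the cohort")
    if (l$value_kind != "zscore") stop("layers must be zscore-standardized")
  }
  withr_seed(seed)
  n <- nrow(cohort)
  u_total <- numeric(n)
  sigma2 <- c()
  for (nm in names(layers)) {
    frac <- if (nm %in% names(true_fractions)) true_fractions[[nm]] else 0
    s2 <- frac * total_var
    sigma2[nm] <- s2
    Z <- layers[[nm]]$values
    q <- ncol(Z)
    w <- stats::rnorm(q, 0, sqrt(s2 / q))
    u <- drop(Z %*% w)
    if (scale_realized && s2 > 0 && stats::sd(u) > 0)
      u <- u * sqrt(s2) / stats::sd(u)
    u_total <- u_total + u
  }
  s2e <- total_var * (1 - sum(true_fractions))
  e <- stats::rnorm(n, 0, sqrt(s2e))
  pe <- parity_effects[((cohort$parity - 1) %% length(parity_effects)) + 1]
  mpy <- mu + pe + dim_slope * cohort$dim + u_total + e
  if (any(mpy <= 0)) mpy <- mpy - min(mpy) + 0.05
  out <- cohort
  out$mpy <- mpy
  n_hh <- attr(cohort, "n_hh") %||% ceiling(n / 2)
  out$group <- ifelse(rank(-mpy, ties.method = "first") <= n_hh, "HH", "LL")
  attr(out, "mpy_filled") <- TRUE
  attr(out, "truth") <- list(seed = seed, n_animals = n,
                             true_fractions = true_fractions,
                             sigma2_layers = sigma2, residual_variance = s2e,
                             total_var = total_var,
                             fixed_effects = list(mu = mu,
                                                  parity_effects = parity_effects,
                                                  dim_slope = dim_slope))
  phenotype_table(as.data.frame(out)) -> res
  attributes(res)[c("n_hh", "mpy_filled", "truth")] <-
    attributes(out)[c("n_hh", "mpy_filled", "truth")]
  res
}

#' One-call synthetic multi-omics cohort
#'
#' Convenience wrapper: covariates, four omics layers, phenotype, truth. The
#' global `seed` expands into fixed per-stage offsets so adding a stage never
#' perturbs earlier stages' randomness.
#'
#' @inheritParams generate_cohort
#' @param true_fractions see [generate_phenotype_from_layers()].
#' @param n_features optional named list overriding per-layer feature counts.
#' @param effect_specs optional named list of per-layer planted effects.
#' @param ... passed to [generate_omics_layer()].
#' @return list with `phenotype` (`PhenotypeTable`, truth attached), `layers`
#'   (named list of raw `FeatureTable`s) and `truth`.
#' @export
simulate_multiomics <- function(seed, n_animals = 16, n_hh = 7,
                                true_fractions = default_true_fractions(),
                                n_features = list(),
                                effect_specs = list(), ...) {
  cohort <- generate_cohort(seed + 1L, n_animals, n_hh)
  layers <- list()
  zlayers <- list()
  for (i in seq_along(LAYER_KINDS)) {
    lk <- LAYER_KINDS[i]
    layers[[lk]] <- generate_omics_layer(
      seed + 1L + i, cohort, lk,
      n_features = n_features[[lk]],
      effect_spec = effect_specs[[lk]] %||% numeric(), ...)
    zlayers[[lk]] <- zscore_standardize(layers[[lk]])
  }
  pheno <- generate_phenotype_from_layers(seed + 6L, cohort, zlayers,
                                          true_fractions = true_fractions)
  list(phenotype = pheno, layers = layers, truth = attr(pheno, "truth"))
}
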