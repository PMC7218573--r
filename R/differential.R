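#' Wilcoxon rank-sum test between two groups
#'
#' Mid-ranks for ties; exact two-sided p by enumeration when both groups
#' have at most `exact_if` observations and there are no ties, otherwise the
#' normal approximation with tie and continuity correction (delegates to
#' [stats::wilcox.test()], which implements exactly this switch).
#'
#' @param x,y numeric observations of the two groups (each n >= 3).
#' @param exact_if maximum group size for the exact enumeration (default 10).
#' @return list with `rank_sum` (of the first group), `U` (Mann-Whitney
#'   statistic), `p`, `exact` flag.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_if = 10) {
  if (length(x) < 3 || length(y) < 3) stop("each group needs at least 3 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && max(length(x), length(y)) <= exact_if
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE))
  U <- unname(wt$statistic)
  list(rank_sum = U + length(x) * (length(x) + 1) / 2, U = U,
       p = min(1, wt$p.value), exact = use_exact)
}

#' LDA effect-size style differential-abundance score
#'
#' Two-stage procedure in the spirit of LEfSe, documented simplified variant
#' for a two-class design without subclasses: (1) per-feature Kruskal-Wallis
#' test (equivalent to Wilcoxon for two groups) at `kw_alpha`; (2) a single
#' regularized two-class Fisher linear discriminant over the surviving
#' features on the per-million abundance scale. The per-feature effect size
#' is `|(w_f * delta_f + delta_f) / 2|`, the average of the
#' discriminant-weighted and the raw class-mean difference (`w` scaled to
#' unit maximum absolute coefficient), and the LDA score is
#' `log10(1 + effect)`. A feature is significant iff `p < kw_alpha` and
#' `lda_score > lda_threshold`. No bootstrap rounds are performed, so scores
#' are comparable in spirit, not bit-identical, to the published LEfSe tool.
#'
#' @param t a `FeatureTable` on a relative/cpm scale (relative abundances are
#'   rescaled to per-million internally; the scale is recorded).
#' @param groups named character vector sample -> group (exactly 2 groups).
#' @param kw_alpha stage-1 alpha (default 0.05).
#' @param lda_threshold minimum LDA score (default 2, per-million scale).
#' @param lambda ridge regularizer as a fraction of `tr(Sw)/q` (default 1e-6).
#' @return data.frame: `feature_id`, `statistic` (KW chi-squared), `p_raw`,
#'   `effect_direction`, `lda_score`, `significant`; attribute `scale`.
#' @export
lefse_style_score <- function(t, groups, kw_alpha = 0.05, lda_threshold = 2,
                              lambda = 1e-6) {
  stopifnot(inherits(t, "FeatureTable"))
  sid <- rownames(t$values)
  g <- factor(groups[sid])
  if (nlevels(g) != 2) stop("exactly two groups are required")
  v <- t$values
  if (t$value_kind == "relative") v <- v * 1e6  # per-million convention
  scale_used <- "per-million"
  q <- ncol(v)
  kw <- vapply(seq_len(q), function(j) {
    k <- stats::kruskal.test(v[, j], g)
    c(k$statistic, k$p.value)
  }, numeric(2))
  stat <- kw[1, ]; p_raw <- kw[2, ]
  means <- rowsum(v, g) / as.vector(table(g))
  delta <- means[1, ] - means[2, ]  # first level minus second
  dir_lab <- ifelse(delta >= 0, levels(g)[1], levels(g)[2])
  surv <- which(!is.na(p_raw) & p_raw < kw_alpha)
  lda_score <- rep(NA_real_, q)
  if (length(surv)) {
    vs <- v[, surv, drop = FALSE]
    centered <- vs - means[g, surv, drop = FALSE]
    Sw <- crossprod(centered) / (nrow(vs) - 2)
    reg <- lambda * sum(diag(Sw)) / length(surv)
    if (reg == 0) reg <- lambda
    w <- solve(Sw + diag(reg, length(surv)), delta[surv])
    w <- w / max(abs(w))
    eff <- abs((w * delta[surv] + delta[surv]) / 2)
    lda_score[surv] <- log10(1 + eff)
  }
  out <- data.frame(feature_id = colnames(v), statistic = stat,
                    p_raw = p_raw, effect_direction = dir_lab,
                    lda_score = lda_score,
                    significant = !is.na(p_raw) & p_raw < kw_alpha &
                      !is.na(lda_score) & lda_score > lda_threshold,
                    row.names = NULL)
  attr(out, "scale") <- scale_used
  out
}

#' PLS-DA variable importance in projection
#'
#' NIPALS partial least squares with a single response column coding the two
#' groups as +/-1 (centered). For feature `f`,
#' `VIP_f = sqrt(q * sum_c(SS_c w_fc^2) / sum_c SS_c)` where `SS_c` is the
#' response variance explained by component `c` and `w_c` the unit-norm
#' weight vector, so `sum_f VIP_f^2 = q` exactly.
#'
#' @param t a `FeatureTable` with `value_kind = "zscore"`.
#' @param groups named character vector sample -> group (exactly 2 groups).
#' @param n_components number of PLS components (default 2; must not exceed
#'   `min(n - 1, q)`).
#' @return named numeric vector of VIP scores (one per feature); attributes
#'   `n_components` and `ss` (per-component explained response SS).
#' @export
plsda_vip <- function(t, groups, n_components = 2) {
  stopifnot(inherits(t, "FeatureTable"))
  if (t$value_kind != "zscore") stop("PLS-DA runs on the zscore table")
  X <- t$values
  sid <- rownames(X)
  g <- factor(groups[sid])
  if (nlevels(g) != 2) stop("exactly two groups are required")
  n <- nrow(X); q <- ncol(X)
  if (n_components > min(n - 1, q))
    stop("n_components exceeds min(n - 1, q)")
  y <- ifelse(g == levels(g)[1], 1, -1)
  y <- y - mean(y)
  W <- matrix(0, q, n_components)
  ss <- numeric(n_components)
  Xc <- X; yc <- y
  for (c in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- c - 1; break }
    w <- w / nw
    tt <- drop(Xc %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) { n_components <- c - 1; break }
    pvec <- drop(crossprod(Xc, tt)) / tt2
    qc <- sum(yc * tt) / tt2
    W[, c] <- w
    ss[c] <- qc^2 * tt2  # response sum of squares explained by component c
    Xc <- Xc - tcrossprod(tt, pvec)
    yc <- yc - qc * tt
  }
  if (n_components < 1) stop("degenerate PLS fit: no usable component")
  W <- W[, seq_len(n_components), drop = FALSE]
  ss <- ss[seq_len(n_components)]
  vip <- sqrt(q * drop(W^2 %*% ss) / sum(ss))
  names(vip) <- colnames(X)
  attr(vip, "n_components") <- n_components
  attr(vip, "ss") <- ss
  vip
}

#' Differential metabolites by Welch t-test + BH FDR + VIP
#'
#' Per-metabolite Welch two-sample t-test, BH-adjusted; PLS-DA VIP on the
#' standardized table; a metabolite is significant iff `q < alpha` and
#' `VIP > vip_threshold` (set `use_raw_p = TRUE` to gate on the raw
#' p-value instead). Metabolites with zero variance in both groups are
#' excluded with a warning. The HH/LL mean fold change gives the direction.
#'
#' @param t a metabolome `FeatureTable` (intensity or zscore; intensities are
#'   standardized internally for the VIP).
#' @param groups named character vector sample -> group (exactly 2 groups;
#'   the first level alphabetically is the numerator of the fold change).
#' @param alpha FDR threshold (default 0.05).
#' @param vip_threshold VIP threshold (default 1).
#' @param n_components PLS components for the VIP (default 2, recorded).
#' @param use_raw_p gate significance on raw p instead of BH q.
#' @return data.frame: `feature_id`, `statistic`, `p_raw`, `q_bh`, `vip`,
#'   `fold_change`, `effect_direction`, `significant`.
#' @export
differential_metabolites <- function(t, groups, alpha = 0.05,
                                     vip_threshold = 1, n_components = 2,
                                     use_raw_p = FALSE) {
  stopifnot(inherits(t, "FeatureTable"))
  sid <- rownames(t$values)
  g <- factor(groups[sid])
  if (nlevels(g) != 2) stop("exactly two groups are required")
  v <- t$values
  # impute missing peaks to the feature mean before testing
  for (j in seq_len(ncol(v))) {
    nas <- is.na(v[, j])
    if (any(nas)) v[nas, j] <- mean(v[!nas, j])
  }
  sd1 <- apply(v[g == levels(g)[1], , drop = FALSE], 2, stats::sd)
  sd2 <- apply(v[g == levels(g)[2], , drop = FALSE], 2, stats::sd)
  usable <- sd1 > 0 | sd2 > 0
  if (any(!usable))
    warning(sum(!usable), " metabolite(s) with zero variance excluded")
  v <- v[, usable, drop = FALSE]
  tt <- vapply(seq_len(ncol(v)), function(j) {
    ht <- stats::t.test(v[g == levels(g)[1], j], v[g == levels(g)[2], j])
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  q_bh <- bh_fdr(tt[2, ])
  zt <- if (t$value_kind == "zscore") {
    feature_table(v, t$layer_kind, "zscore", t$feature_meta)
  } else {
    suppressWarnings(zscore_standardize(
      feature_table(v, t$layer_kind, t$value_kind, t$feature_meta)))
  }
  vip <- plsda_vip(zt, groups, n_components = n_components)
  vip_full <- vip[colnames(v)]
  m1 <- colMeans(v[g == levels(g)[1], , drop = FALSE])
  m2 <- colMeans(v[g == levels(g)[2], , drop = FALSE])
  fc <- m1 / m2
  p_gate <- if (use_raw_p) tt[2, ] else q_bh
  data.frame(feature_id = colnames(v), statistic = tt[1, ], p_raw = tt[2, ],
             q_bh = q_bh, vip = unname(vip_full), fold_change = fc,
             effect_direction = ifelse(m1 >= m2, levels(g)[1], levels(g)[2]),
             significant = p_gate < alpha & !is.na(vip_full) &
               vip_full > vip_threshold,
             row.names = NULL)
}
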