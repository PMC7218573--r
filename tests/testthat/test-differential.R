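test_that("wilcoxon exact p equals brute-force enumeration; approx agrees", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p, 2 / 20)  # 2 of C(6,3)=20 assignments are as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # enumeration oracle across random no-tie instances up to (6,6)
  set.seed(800)
  for (i in 1:15) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(1:100, n1 + n2)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_brute(x, y),
                 tolerance = 1e-12)
  }
  # exact and normal-approximation p agree within 0.02 at (7, 9)
  set.seed(801)
  v <- sample(1:1000, 16)
  x <- v[1:7]; y <- v[8:16]
  p_exact <- wilcoxon_rank_sum(x, y, exact_if = 10)$p
  p_approx <- wilcoxon_rank_sum(x, y, exact_if = 5)$p
  expect_false(wilcoxon_rank_sum(x, y, exact_if = 5)$exact)
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(wilcoxon_rank_sum(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("LDA-style scores flag planted features and respect the gate", {
  set.seed(810)
  n <- 16
  g <- stats::setNames(rep(c("HH", "LL"), c(7, 9)), sprintf("cow%03d", 1:n))
  v <- matrix(rexp(n * 20, rate = 1e-3), n, 20,
              dimnames = list(names(g), sprintf("ko_%03d", 1:20)))
  # planted feature: ~30,000 vs ~10,000 per-million, low noise
  v[, 1] <- c(rnorm(7, 30000, 1500), rnorm(9, 10000, 800))
  v[, 2] <- rep(5000, n) + rnorm(n, 0, 1)  # near-identical across groups
  t1 <- feature_table(v, "function", "intensity")
  res <- lefse_style_score(t1, g)
  expect_true(res$significant[1])
  expect_gt(res$lda_score[1], 2)
  expect_equal(res$effect_direction[1], "HH")
  expect_false(isTRUE(res$significant[2]))
  # identical feature across groups fails stage 1
  v2 <- v; v2[, 3] <- 7
  res2 <- suppressWarnings(lefse_style_score(
    feature_table(v2, "function", "intensity"), g))
  expect_false(res2$significant[3])
  # invariant to feature order
  perm <- sample(20)
  res_p <- lefse_style_score(feature_table(v[, perm], "function", "intensity"), g)
  expect_equal(res_p$lda_score[match(res$feature_id, res_p$feature_id)],
               res$lda_score, tolerance = 1e-8)
})

test_that("label-permuted data keeps the LDA-score flag rate near alpha", {
  set.seed(820)
  n <- 20
  flagged <- replicate(60, {
    g <- stats::setNames(sample(rep(c("HH", "LL"), each = 10)),
                         sprintf("cow%03d", 1:n))
    v <- matrix(rexp(n * 25, rate = 1e-4), n, 25,
                dimnames = list(names(g), sprintf("ko_%03d", 1:25)))
    mean(suppressWarnings(
      lefse_style_score(feature_table(v, "function", "intensity"), g))$significant)
  })
  expect_lte(mean(flagged), 0.05 + 0.02)
})

test_that("VIP satisfies its normalization identity and ranks separators", {
  sim <- simulate_multiomics(33)
  g <- stats::setNames(sim$phenotype$group, sim$phenotype$sample_id)
  z <- suppressWarnings(zscore_standardize(sim$layers$rumen_metabolome))
  vip <- plsda_vip(z, g, n_components = 2)
  q <- ncol(z$values)
  expect_equal(sum(vip^2), q, tolerance = 1e-6)
  expect_equal(attr(vip, "n_components"), 2)
  # q = 1 forces VIP = 1
  z1 <- feature_table(z$values[, 1, drop = FALSE], "rumen_metabolome", "zscore")
  expect_equal(as.numeric(plsda_vip(z1, g, 1)), 1, tolerance = 1e-9)
  # one perfect separator vs pure noise: separator VIP > 1 > noise VIP
  set.seed(830)
  n <- 20
  gg <- stats::setNames(rep(c("HH", "LL"), each = 10), paste0("s", 1:n))
  sep <- scale(c(rnorm(10, 3, 0.1), rnorm(10, -3, 0.1)))[, 1]
  noise <- scale(rnorm(n))[, 1]
  zz <- feature_table(cbind(sep = sep, noise = noise) |>
                        (\(m) { rownames(m) <- names(gg); m })(),
                      "rumen_metabolome", "zscore")
  vip2 <- plsda_vip(zz, gg, n_components = 1)
  expect_gt(vip2["sep"], 1)
  expect_lt(vip2["noise"], 1)
  # 1-component closed form: weights proportional to feature-response cov
  w <- abs(c(cov(sep, c(rep(1, 10), rep(-1, 10))),
             cov(noise, c(rep(1, 10), rep(-1, 10)))))
  expect_equal(order(vip2), order(w))
  expect_error(plsda_vip(zz, gg, n_components = 10), "exceeds")
})

test_that("VIP agrees with the mixOmics reference implementation", {
  set.seed(840)
  n <- 14
  g <- stats::setNames(rep(c("HH", "LL"), each = 7), paste0("s", 1:n))
  z <- suppressWarnings(zscore_standardize(
    feature_table(matrix(rexp(n * 9), n, 9,
                         dimnames = list(names(g), paste0("f", 1:9))),
                  "rumen_metabolome", "intensity")))
  vip_mine <- plsda_vip(z, g, n_components = 2)
  pl <- mixOmics::plsda(z$values, factor(g), ncomp = 2, scale = FALSE)
  vip_ref <- mixOmics::vip(pl)[, 2]
  expect_equal(as.numeric(vip_mine), as.numeric(vip_ref[names(vip_mine)]),
               tolerance = 1e-6)
})

test_that("differential metabolites combine Welch t, BH and VIP correctly", {
  set.seed(850)
  n <- 60
  g <- stats::setNames(rep(c("HH", "LL"), each = 30), sprintf("cow%03d", 1:n))
  q <- 210
  v <- matrix(rlnorm(n * q, 5, 0.3), n, q,
              dimnames = list(names(g), sprintf("rmet_%03d", 1:q)))
  planted <- 1:10
  v[g == "HH", planted] <- v[g == "HH", planted] * 2  # 2-fold planted shift
  v[, q] <- 42  # constant -> excluded
  t1 <- feature_table(v, "rumen_metabolome", "intensity")
  expect_warning(res <- differential_metabolites(t1, g), "zero variance")
  expect_false("rmet_210" %in% res$feature_id)
  expect_gte(sum(res$significant[match(sprintf("rmet_%03d", planted),
                                       res$feature_id)]), 7)
  nulls <- setdiff(seq_len(q - 1), planted)
  false_rate <- mean(res$significant[match(sprintf("rmet_%03d", nulls),
                                           res$feature_id)])
  expect_lte(false_rate, 0.05)
  expect_true(all(res$fold_change[match(sprintf("rmet_%03d", planted),
                                        res$feature_id)] > 1))
  expect_true(all(res$effect_direction[match(sprintf("rmet_%03d", planted),
                                             res$feature_id)] == "HH"))
  # alpha = 0 gates everything out
  res0 <- suppressWarnings(differential_metabolites(t1, g, alpha = 0))
  expect_false(any(res0$significant))
})
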