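test_that("spearman matches the d^2 formula, cor.test, and handles ties", {
  s <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 1 - 6 * 2 / (4 * 15))  # classic d^2 formula: 0.8
  rev <- spearman_cor(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(rev$rho, -1)
  expect_true(rev$exact_monotone)
  expect_gt(rev$p, 0)
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
  expect_error(spearman_cor(1:4, rep(2, 4)), "zero variance")
  # ties-containing vectors: rho equals rank-then-Pearson and cor(method)
  set.seed(700)
  for (i in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    s2 <- spearman_cor(x, y)
    expect_equal(s2$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(s2$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(s2$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("spearman screening attains nominal size on independent pairs", {
  set.seed(710)
  rejections <- vapply(1:2000, function(i) {
    spearman_cor(rnorm(16), rnorm(16))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("metabotype screening classifies signs and recovers planted signals", {
  sim <- simulate_multiomics(31)
  # metabolite equal to MPY -> perfect positive; a reversed copy -> negative
  v <- sim$layers$rumen_metabolome$values
  v[, 1] <- sim$phenotype$mpy
  v[, 2] <- max(sim$phenotype$mpy) + 1 - sim$phenotype$mpy
  met2 <- feature_table(v, "rumen_metabolome", "intensity")
  scr <- suppressWarnings(screen_metabotypes(met2, sim$phenotype))
  expect_equal(scr$sign_class[1], "MPY-positive")
  expect_equal(scr$sign_class[2], "MPY-negative")
  expect_equal(scr$rho[1], 1)

  # planted metabotypes at |rho| ~ 0.8, n = 60: >= 16/20 recovered with sign
  set.seed(720)
  n <- 60
  mpy <- rnorm(n, 1.2, 0.3)
  q <- 60
  m <- matrix(rnorm(n * q), n, q,
              dimnames = list(sprintf("cow%03d", 1:n), sprintf("rmet_%03d", 1:q)))
  planted <- 1:20
  for (j in planted) m[, j] <- scale(mpy)[, 1] * 0.8 + rnorm(n, 0, 0.6)
  m <- m + 10
  ph <- phenotype_table(data.frame(sample_id = rownames(m), mpy = mpy,
                                   parity = 1, dim = 100))
  scr2 <- screen_metabotypes(feature_table(m, "rumen_metabolome", "intensity"), ph)
  hits <- scr2$sign_class[planted] == "MPY-positive"
  expect_gte(sum(hits), 16)

  # constant columns are excluded with a warning
  m[, q] <- 5
  expect_warning(
    scr3 <- screen_metabotypes(feature_table(m, "rumen_metabolome", "intensity"), ph),
    "excluded")
  expect_equal(nrow(scr3), q - 1)
})

test_that("PERMANOVA agrees with vegan, enumeration, and its invariances", {
  set.seed(730)
  v <- matrix(rexp(4 * 6), 4, 6, dimnames = list(paste0("s", 1:4), NULL))
  colnames(v) <- paste0("f", 1:6)
  d <- bray_curtis(ft(v))
  z <- c(0.3, -1.2, 0.5, 2.0)
  pr <- permanova(d, z, n_perm = 10000, seed = 1)
  # pseudo-F by explicit hat-matrix brute force and by vegan::adonis2
  expect_equal(pr$pseudo_F, permanova_f_brute(d$values, z), tolerance = 1e-10)
  ad <- vegan::adonis2(stats::as.dist(d$values) ~ z, permutations = 99)
  expect_equal(pr$pseudo_F, ad$F[1], tolerance = 1e-8)
  # Monte-Carlo p within 0.02 of the full 4! enumeration
  expect_lt(abs(pr$p - permanova_p_enum(d$values, z)), 0.02)
  # invariant to adding a constant to the covariate
  pr2 <- permanova(d, z + 100, n_perm = 999, seed = 5)
  pr2b <- permanova(d, z, n_perm = 999, seed = 5)
  expect_equal(pr2$pseudo_F, pr2b$pseudo_F, tolerance = 1e-10)
  expect_equal(pr2$p, pr2b$p)
  # consistent permutation of distances and covariate leaves p unchanged
  perm <- c(3, 1, 4, 2)
  dp <- structure(list(values = d$values[perm, perm]), class = "DistanceMatrix")
  pr3 <- permanova(dp, z[perm], n_perm = 999, seed = 7)
  pr3b <- permanova(d, z, n_perm = 999, seed = 7)
  expect_equal(pr3$pseudo_F, pr3b$pseudo_F, tolerance = 1e-10)
  expect_error(permanova(d, rep(1, 4)), "constant")
  expect_error(permanova(d, z, n_perm = 10), "at least 99")
})

test_that("an extreme covariate reaches the minimum attainable PERMANOVA p", {
  # the first principal coordinate maximizes the explained inertia over all
  # covariate vectors, so every permutation scores strictly lower and the
  # add-one p-value hits its floor 1/(1 + n_perm)
  set.seed(740)
  v <- rbind(matrix(rexp(5 * 4, rate = 1), 5, 4),
             matrix(rexp(5 * 4, rate = 1) + 50, 5, 4))
  rownames(v) <- paste0("s", 1:10); colnames(v) <- paste0("f", 1:4)
  d <- bray_curtis(ft(v))
  ax1 <- pcoa(d, k = 1)$coordinates[, 1]
  pr <- permanova(d, ax1, n_perm = 999, seed = 2)
  expect_equal(pr$p, 1 / (1 + 999))
})

test_that("BH q-values match the brute-force tail-min step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  set.seed(750)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
  # stable under input permutation
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("composed metabotype pipeline flags latent-linked metabolites", {
  # one latent factor drives both the taxa table and the planted metabolites
  set.seed(760)
  n <- 24
  latent <- rnorm(n)
  taxa <- matrix(rexp(n * 40), n, 40)
  taxa[, 1:10] <- taxa[, 1:10] * exp(0.8 * latent)  # latent shifts community
  rownames(taxa) <- sprintf("cow%03d", 1:n)
  colnames(taxa) <- sprintf("sp_%03d", 1:40)
  d <- bray_curtis(to_relative_abundance(ft(taxa)))
  q <- 30
  m <- matrix(rnorm(n * q), n, q,
              dimnames = list(rownames(taxa), sprintf("rmet_%03d", 1:q)))
  planted <- 1:10
  for (j in planted) m[, j] <- latent + rnorm(n, 0, 0.5)
  m <- m + 10
  mpy <- exp(0.2 + 0.4 * latent + rnorm(n, 0, 0.25))  # latent drives MPY too
  ph <- phenotype_table(data.frame(sample_id = rownames(taxa), mpy = mpy,
                                   parity = 1, dim = 100))
  res <- metabotype_analysis(feature_table(m, "rumen_metabolome", "intensity"),
                             ph, d, n_perm = 199, seed = 3)
  recall <- mean(res$microbiome_responsive[planted])
  expect_gte(recall, 0.7)
  # invariant: responsive implies screened and q below threshold
  flagged <- which(res$microbiome_responsive)
  expect_true(all(res$sign_class[flagged] != "none"))
  expect_true(all(res$q_permanova[flagged] < 0.05))
})

test_that("correlation networks keep only strong significant cross-edges", {
  set.seed(770)
  n <- 16
  a <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(paste0("s", 1:n), paste0("sp", 1:5)))
  b <- matrix(rnorm(n * 4), n, 4, dimnames = list(paste0("s", 1:n), paste0("met", 1:4)))
  b[, 1] <- a[, 2]  # duplicated column -> rho = 1 edge
  ta <- feature_table(a + 10, "taxa", "intensity")
  tb <- feature_table(b + 10, "rumen_metabolome", "intensity")
  net <- build_correlation_network(ta, tb)
  expect_true(any(net$node_a == "sp2" & net$node_b == "met1" &
                    abs(net$rho - 1) < 1e-12))
  # vacuous threshold empties the list
  expect_equal(nrow(build_correlation_network(ta, tb, r_threshold = 1.01)), 0)
  # edges sorted by (node_a, node_b)
  expect_false(is.unsorted(net$node_a))
  # null tables: retained fraction near the simulated null expectation
  set.seed(771)
  nullfrac <- replicate(40, {
    x <- matrix(rexp(16 * 10), 16, 10,
                dimnames = list(paste0("s", 1:16), paste0("a", 1:10)))
    y <- matrix(rexp(16 * 10), 16, 10,
                dimnames = list(paste0("s", 1:16), paste0("b", 1:10)))
    nrow(build_correlation_network(
      feature_table(x, "taxa", "intensity"),
      feature_table(y, "rumen_metabolome", "intensity"))) / 100
  })
  # P(|rho| > 0.5 and p < 0.05) at n = 16 is a few percent; the observed mean
  # must sit inside a generous binomial envelope of the simulated expectation
  expect_lt(mean(nullfrac), 0.15)
})
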