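# Shared fixture: the default synthetic study, fully derived.
features_fixture <- local({
  b <- simulate_study(default_design(), seed = 101,
                      tables = c("enzymes", "chemistry", "biomass",
                                 "respiration"))
  chem <- derive_chemistry(b$chemistry)
  stoich <- cbind(eea_summary(b$enzymes),
                  b$enzymes[c("alkaline_phosphatase", "arylsulphatase")])
  micro <- microbial_summary(b$biomass, b$respiration, chem)
  assemble_features(stoich, chem, micro)
})

test_that("the assembled feature matrix has the 25 z-scored variables", {
  x <- features_fixture
  expect_equal(dim(x), c(15, 25))
  expect_equal(unname(colMeans(x)), rep(0, 25), tolerance = 1e-9)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 25), tolerance = 1e-9)
  expect_equal(length(attr(x, "groups")), 15)
  expect_equal(sum(attr(x, "roles") == "chemical"), 12)
  expect_false(any(c("CFU", "MPN", "TDE", "EPI") %in% colnames(x)))
})

test_that("PCA conserves variance, reconstructs the data and fixes signs", {
  x <- features_fixture
  p <- pca_ordination(x)
  expect_equal(sum(p$prop_var), 1)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$eigenvalues), sum(apply(x, 2, var)), tolerance = 1e-8)
  # scores %*% t(loadings) recovers the centred matrix
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, sweep(x, 2, colMeans(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: the dominant loading on each axis is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # two perfectly correlated variables load a single component
  twin <- cbind(a = scale(1:10)[, 1], b = scale((1:10) * 2)[, 1])
  expect_equal(pca_ordination(twin)$prop_var[1], 1)
})

test_that("component tests resolve a clean three-group separation", {
  set.seed(41)
  scores <- cbind(PC1 = rep(c(0, 10, 20), each = 5) + rnorm(15, 0, 0.01),
                  PC2 = rnorm(15, 0, 0.01))
  groups <- rep(c("a", "b", "c"), each = 5)
  ct <- component_tests(scores, groups)
  expect_lt(ct$PC1$anova_p, 1e-6)
  expect_true(all(ct$PC1$tukey$p_adjusted < 1e-4))
  expect_lt(ct$PC1$kruskal_p, 0.01)
  expect_true(all(c("shapiro_p", "levene_p", "dunn") %in% names(ct$PC1)))
  expect_equal(nrow(ct$PC1$dunn), 3)
  expect_match(component_tests(scores[1:2, , drop = FALSE],
                               groups[c(1, 6)])$PC1, "skipped")
})

test_that("Dunn statistics agree with direct rank arithmetic on a known case", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_test(x, g)
  # no ties: SE = sqrt(N(N+1)/12 * 2/3), mean rank gap a vs c = 6
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  expect_equal(d$z[d$comparison == "a-c"], -6 / se)
  expect_equal(d$p_adjusted, pmin(1, d$p_value * 3))
})

test_that("k-means recovers well-separated groups and purity is label-invariant", {
  set.seed(42)
  scores <- rbind(matrix(rnorm(10, 0, 0.1), 5),
                  matrix(rnorm(10, 5, 0.1), 5),
                  matrix(rnorm(10, 10, 0.1), 5))
  groups <- rep(c("a", "b", "c"), each = 5)
  km <- kmeans_clusters(scores, groups, k = 3, seed = 7)
  expect_equal(km$purity, 1)
  expect_equal(sort(km$sizes), c(5, 5, 5))
  km1 <- kmeans_clusters(scores, groups, k = 1, seed = 7)
  expect_equal(km1$purity, 1 / 3)
  # relabelling clusters does not change purity
  perm <- c(2, 3, 1)[km$cluster]
  expect_equal(cluster_purity(perm, groups), km$purity)
  expect_error(kmeans_clusters(scores, groups, k = 99), "exceed")
})

test_that("Spearman matrix matches the rank-based oracle and flags constants", {
  x <- c(2.1, 5.3, 0.4, 9.9, 7.7, 3.2)
  y <- c(1.0, 2.2, 0.1, 9.4, 3.3, 8.8)
  sm <- spearman_matrix(cbind(x = x), cbind(y = y))
  expect_equal(sm$rho["x", "y"], spearman_rank_oracle(x, y))
  expect_equal(spearman_matrix(cbind(a = 1:5),
                               cbind(b = (1:5)^3))$rho[1, 1], 1)
  expect_equal(spearman_matrix(cbind(a = 1:5),
                               cbind(b = 5:1))$rho[1, 1], -1)
  cm <- spearman_matrix(cbind(a = rep(1, 5)), cbind(b = 1:5))
  expect_true(is.na(cm$rho[1, 1]))
})

test_that("VIF screening drops collinear variables deterministically", {
  set.seed(43)
  a <- rnorm(20); b <- rnorm(20)
  keep <- vif_screen(data.frame(a = a, b = b))
  expect_equal(sort(keep$selected), c("a", "b"))
  expect_true(all(keep$vifs < 1.5))

  dup <- vif_screen(data.frame(a = a, b = b, a2 = a))
  expect_equal(length(dup$dropped), 1)
  expect_equal(dup$dropped, "a") # lexicographic tie-break among duplicates
  expect_true(all(dup$vifs < 2))

  combo <- vif_screen(data.frame(a = a, b = b, c = a + b))
  expect_equal(length(combo$dropped), 1)
  expect_true(all(combo$vifs < 2))
  expect_equal(vif_screen(data.frame(a = a))$vifs, c(a = 1))
})

test_that("redundancy analysis partitions variance and rejects exact collinearity", {
  set.seed(44)
  y <- matrix(rnorm(60 * 6), 60)
  y <- base::scale(y)
  env <- data.frame(e1 = y[, 1])
  r <- rda_analysis(y, env, n_perm = 99, seed = 1)
  # a single response column as its own predictor explains at least its own
  # variance share, plus only a small chance contribution from the others
  share <- sum(y[, 1]^2) / sum(y^2)
  expect_gte(r$constrained_prop, share)
  expect_lt(r$constrained_prop, share + 0.06)
  expect_equal(sum(r$axis_prop), 1)
  expect_error(rda_analysis(y, data.frame(a = y[, 1], b = 2 * y[, 1]),
                            n_perm = 99), "collinear")
  # seeded permutation p-values reproduce
  r2 <- rda_analysis(y, env, n_perm = 99, seed = 1)
  expect_identical(r$p_global, r2$p_global)
})

test_that("PERMANOVA matches exhaustive enumeration on a tiny two-group instance", {
  set.seed(45)
  x <- matrix(rnorm(6 * 3), 6)
  x[4:6, ] <- x[4:6, ] + 1.5
  g <- rep(c("a", "b"), each = 3)
  mine <- permanova(x, g, exhaustive = TRUE)
  oracle <- permanova_enum_oracle(x, g)
  expect_equal(mine$F, oracle$f)
  expect_equal(mine$p_value, oracle$p)
  expect_true(mine$R2 > 0 && mine$R2 < 1)
})

test_that("PERMANOVA is reproducible, rotation-invariant and near-null on shuffled labels", {
  x <- features_fixture
  g <- attr(x, "groups")
  p1 <- permanova(x, g, n_perm = 199, seed = 9)
  p2 <- permanova(x, g, n_perm = 199, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$F, p2$F)

  # an orthogonal rotation preserves Euclidean distances, hence F and R2
  q <- qr.Q(qr(matrix(rnorm(25 * 25), 25)))
  pr <- permanova(x %*% q, g, n_perm = 199, seed = 9)
  expect_equal(pr$F, p1$F, tolerance = 1e-8)
  expect_equal(pr$R2, p1$R2, tolerance = 1e-8)
  expect_identical(pr$p_value, p1$p_value)

  set.seed(46)
  gs <- sample(g)
  ps <- permanova(x, gs, n_perm = 199, seed = 9)
  expect_lt(ps$R2, p1$R2)
  expect_gt(ps$p_value, 0.05)
  expect_equal(sum(p1$ss[c("among", "within")]), p1$ss[["total"]])
})

test_that("PERMANOVA R2 and F agree with the reference implementation", {
  x <- features_fixture
  g <- attr(x, "groups")
  mine <- permanova(x, g, n_perm = 199, seed = 9)
  ref <- vegan::adonis2(dist(x) ~ g, permutations = 199)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-8)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-8)
})
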