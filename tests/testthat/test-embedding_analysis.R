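toy_embeddings <- function(n = 50, d = 6, seed = 1L)
  with_seed(seed, matrix(rnorm(n * d), n, d) %*% diag(seq(3, 0.5, length.out = d)))

test_that("fit_pca: orthonormal basis, variance ordering, eigen-oracle", {
  E <- toy_embeddings()
  b <- fit_pca(E)
  G <- t(b$loadings) %*% b$loadings
  expect_equal(unname(G), diag(2), tolerance = 1e-8)
  expect_gte(b$var_explained[1], b$var_explained[2])
  expect_true(all(b$var_explained >= 0 & b$var_explained <= 1))
  # sign convention: largest-magnitude coefficient positive
  for (j in 1:2) expect_gt(b$loadings[which.max(abs(b$loadings[, j])), j], 0)
  # eigen-oracle on a 5-point set
  X <- matrix(c(1, 2, 4, 7, 11,
                2, 1, 3, 8, 10,
                0, 1, 2, 2, 4), 5, 3)
  bb <- fit_pca(X)
  ev <- eigen(cov(X))$values
  pc1_var <- var((scale(X, center = TRUE, scale = FALSE) %*% bb$loadings)[, 1])
  expect_equal(pc1_var, ev[1], tolerance = 1e-10)
  # 2-D input: total variance of the two PCs equals total variance
  X2 <- toy_embeddings(40, 2, 3L)
  b2 <- fit_pca(X2)
  expect_equal(sum(b2$var_explained), 1, tolerance = 1e-12)
  expect_error(fit_pca(matrix(1, 10, 4)), "degenerate|rank")
  expect_error(fit_pca(matrix(rnorm(4), 2, 2)), "3 rows")
})

test_that("project_embeddings: center maps to origin; oracle matrix product; errors", {
  E <- toy_embeddings()
  b <- fit_pca(E)
  pc <- project_embeddings(E, b)
  expect_equal(mean(pc$PC1), 0, tolerance = 1e-10)
  expect_equal(mean(pc$PC2), 0, tolerance = 1e-10)
  center_pt <- matrix(b$center, 1)
  expect_equal(unlist(project_embeddings(center_pt, b)), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-12)
  # second group equals an independent matrix-product oracle
  G2 <- toy_embeddings(20, 6, 9L) + 1
  pc2 <- project_embeddings(G2, b)
  oracle <- sweep(G2, 2, b$center) %*% b$loadings
  expect_equal(pc2$PC1, oracle[, 1], tolerance = 1e-12)
  expect_equal(pc2$PC2, oracle[, 2], tolerance = 1e-12)
  expect_error(project_embeddings(G2[, 1:3], b), "dimensionality")
  # affine equivariance: a constant shift leaves PC coordinates unchanged
  b_shift <- fit_pca(E + 5)
  pc_shift <- project_embeddings(E + 5, b_shift)
  expect_equal(pc_shift, pc, tolerance = 1e-8)
})

test_that("kde_map: integral 1, mode at cluster, closed-form normal check", {
  pc <- with_seed(4L, data.frame(PC1 = rnorm(200), PC2 = rnorm(200)))
  km <- kde_map(pc, bandwidth_adjust = 1)
  integral <- sum(km$z) * diff(km$x[1:2]) * diff(km$y[1:2])
  expect_lt(abs(integral - 1), 0.02)
  # density at the true mean within 20% of closed form 1/(2 pi)
  i <- which.min(abs(km$x)); j <- which.min(abs(km$y))
  expect_lt(abs(km$z[i, j] - 1 / (2 * pi)) / (1 / (2 * pi)), 0.2)
  # tight cluster: mode within one grid cell of the centroid
  tight <- with_seed(5L, data.frame(PC1 = rnorm(50, 3, 0.01),
                                    PC2 = rnorm(50, -2, 0.01)))
  kt <- kde_map(tight)
  w <- which(kt$z == max(kt$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(kt$x[w[1]] - 3), diff(kt$x[1:2]) * 1.5)
  expect_lt(abs(kt$y[w[2]] + 2), diff(kt$y[1:2]) * 1.5)
  # threshold semantics: lowest contour level at 10% of max density
  expect_equal(min(kt$levels), 0.1 * max(kt$z), tolerance = 1e-12)
  expect_error(kde_map(pc[1:5, ]), "at least 10")
})

test_that("threshold_rule builds named conjunctions and validates", {
  r <- threshold_rule(pc1_gt = 50)
  expect_identical(r$name, "PC1 > 50")
  r2 <- threshold_rule(pc1_gt = 100, pc2_gt = 0)
  expect_identical(r2$name, "PC1 > 100 & PC2 > 0")
  expect_error(threshold_rule(), "at least one")
  expect_error(threshold_rule(pc1_gt = Inf))
})

test_that("threshold_proportions: hand counts, identical groups, clamped CI", {
  pc <- data.frame(PC1 = c(1, 2, 3, 10, 11, 1, 2, 3, 10, 12),
                   PC2 = rep(0, 10))
  grp <- rep(c("a", "b"), each = 5)
  res <- threshold_proportions(pc, grp, threshold_rule(pc1_gt = 5))
  expect_equal(res$proportions$proportion, c(0.4, 0.4))
  expect_equal(res$proportions$k, c(2, 2))
  expect_equal(res$tests$z, 0)
  expect_equal(res$tests$p_value, 1)
  # all below threshold: proportion 0, lower bound clamped to 0
  res0 <- threshold_proportions(pc, grp, threshold_rule(pc1_gt = 100))
  expect_equal(res0$proportions$proportion, c(0, 0))
  expect_equal(res0$proportions$ci_lower, c(0, 0))
  expect_equal(res0$tests$p_value, 1)  # degenerate pooled proportion
  expect_error(threshold_proportions(pc, grp, threshold_rule(pc1_gt = 5),
                                     pairs = list(c("a", "zzz"))), "unknown")
})

test_that("axis_outlier_counts: first-match accounting reproduces planted counts", {
  # planted outliers: 145 with PC1 > 300, 32 with PC2 > 40, 823 inliers
  pc <- with_seed(8L, data.frame(
    PC1 = c(runif(145, 301, 500), runif(32, -50, 250), runif(823, -50, 250)),
    PC2 = c(runif(145, -10, 30), runif(32, 41, 80), runif(823, -10, 30))))
  out <- axis_outlier_counts(pc, list(pc1_max = 300, pc2_max = 40))
  expect_identical(unname(out$per_rule), c(145L, 32L))
  expect_identical(out$total, 177L)
  expect_identical(sum(out$keep), 823L)
  # limits beyond range exclude nothing
  none <- axis_outlier_counts(pc, list(pc1_max = 1e6, pc2_min = -1e6))
  expect_identical(none$total, 0L)
  # overlapping rules: first-match disjoint accounting equals brute force
  pc2 <- data.frame(PC1 = c(400, 400, 100), PC2 = c(50, 10, 50))
  o2 <- axis_outlier_counts(pc2, list(pc1_max = 300, pc2_max = 40))
  expect_identical(unname(o2$per_rule), c(2L, 1L))
  expect_identical(o2$total, 3L)
  o3 <- axis_outlier_counts(pc2, list(pc2_max = 40, pc1_max = 300))
  expect_identical(unname(o3$per_rule), c(2L, 1L))
})

test_that("quantile_threshold_rule picks the held-out quantile", {
  pc <- data.frame(PC1 = 1:100, PC2 = rep(0, 100))
  r <- quantile_threshold_rule(pc, "PC1", 0.9)
  expect_equal(r$parts$pc1_gt, quantile(1:100, 0.9, names = FALSE))
})
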