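test_that("inter-sampling intervals average consecutive paid touches", {
  expect_equal(inter_sampling_interval(c(2, 5, 9.5)), 3.75)
  expect_equal(inter_sampling_interval(seq(0.5, 10, by = 1.9)), 1.9)
  expect_message(isi1 <- inter_sampling_interval(3.2), "undefined")
  expect_true(is.na(isi1))
  expect_error(inter_sampling_interval(c(5, 2)), "ordered")
})

test_that("subjective uncertainty is sign-flipped z-scored confidence", {
  expect_equal(subjective_uncertainty(c(2, 4)),
               c(1, -1) / sqrt(2), tolerance = 1e-12)
  set.seed(4)
  ratings <- sample(1:10, 40, replace = TRUE)
  su <- subjective_uncertainty(ratings)
  expect_equal(mean(su), 0, tolerance = 1e-12)
  expect_equal(sd(su), 1, tolerance = 1e-12)
  expect_equal(su, subjective_uncertainty(ratings + 3))  # location invariant
  expect_true(all(diff(su[order(ratings)]) <= 1e-12 |
                    diff(sort(ratings)) > 0))
  expect_lt(cor(ratings, su), 0)
  expect_warning(z0 <- subjective_uncertainty(rep(5, 10)), "constant")
  expect_equal(z0, rep(0, 10))
})

test_that("affective burden matches the two-variable PCA identity", {
  # for two standardised variables PC1 carries (1 + |r|) / 2 of the variance
  set.seed(88)
  x <- rnorm(200)
  y <- 0.6 * x + 0.8 * rnorm(200)
  ab <- affective_burden(x, y)
  expect_equal(ab$variance_explained,
               100 * (1 + abs(cor(x, y))) / 2, tolerance = 1e-9)
  expect_gt(cor(ab$scores, x), 0)  # oriented with the inputs
  expect_gt(cor(ab$scores, y), 0)
  # perfectly correlated pair is rank one; anticorrelated pair matches |r|
  expect_equal(affective_burden(1:10, 2 * (1:10) + 3)$variance_explained, 100)
  ab_neg <- affective_burden(x, -y)
  expect_equal(ab_neg$variance_explained, ab$variance_explained)
  # independent standardised pair: isotropic, PC1 -> 50%
  set.seed(99)
  big <- affective_burden(rnorm(20000), rnorm(20000))
  expect_equal(big$variance_explained, 50, tolerance = 0.03)
  expect_error(affective_burden(1:2, 1:2), "at least 3")
})

test_that("partial Spearman agrees with the recursive formula on ranks", {
  x <- c(3.1, 7.4, 1.2, 9.9, 5.5, 2.8, 8.1, 4.4)
  z <- c(0.2, 1.7, 0.9, 2.5, 1.1, 0.4, 2.2, 1.4)
  y <- c(2.0, 6.5, 2.1, 8.8, 4.9, 3.0, 7.7, 5.1)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- cor(rx, ry); r_xz <- cor(rx, rz); r_yz <- cor(ry, rz)
  oracle <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  set.seed(1)
  ps <- partial_spearman(x, y, z, n_perm = 100)
  expect_equal(ps$rho, oracle, tolerance = 1e-12)
  # a deterministic monotone relation survives any covariate
  set.seed(2)
  xx <- rnorm(30)
  expect_equal(partial_spearman(xx, exp(xx), rnorm(30), n_perm = 100)$rho,
               1, tolerance = 1e-9)
  expect_error(partial_spearman(x, y, cbind(z, z)), "rank-deficient")
})

test_that("the partial-correlation permutation test holds its size", {
  set.seed(404)
  hits <- mean(replicate(300, {
    x <- rnorm(60)
    y <- rnorm(60)
    partial_spearman(x, y, rnorm(60), n_perm = 200)$p_value < 0.05
  }))
  expect_gt(hits, 0.015)
  expect_lt(hits, 0.10)
})

test_that("permutation group contrasts detect shifts and respect symmetry", {
  set.seed(77)
  a <- rnorm(27)
  b <- rnorm(27) + 2  # 2-SD shift
  vals <- c(a, b)
  grp <- rep(c("control", "SCI"), each = 27)
  set.seed(5)
  ct <- permutation_group_contrast(vals, grp, n_perm = 2000)
  expect_lt(ct$p_value, 0.01)
  means <- c(control = mean(a), SCI = mean(b))
  expect_equal(ct$mean_difference,
               unname(means[ct$levels[1]] - means[ct$levels[2]]))
  set.seed(5)
  flipped <- permutation_group_contrast(vals, rev(grp), n_perm = 2000)
  expect_equal(abs(flipped$mean_difference), abs(ct$mean_difference))
  # identical groups differ by zero
  same <- permutation_group_contrast(rep(c(1, 2, 3), 4),
                                     rep(c("a", "b"), each = 6))
  expect_equal(same$mean_difference, 0)
  expect_error(permutation_group_contrast(1:5, rep("a", 5)), "two levels")
})

test_that("Bonferroni thresholds divide the family-wise rate", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(2), 0.025)
  expect_equal(bonferroni_threshold(10, alpha = 0.1), 0.01)
})
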