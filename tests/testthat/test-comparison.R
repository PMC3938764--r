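test_that("CVA matches the two-class LDA direction", {
  set.seed(6)
  x <- matrix(rnorm(400 * 4), 400, 4)
  grp <- rep(c("a", "b"), each = 200)
  x[grp == "b", 1] <- x[grp == "b", 1] + 3    # separation along e1 only
  f <- cva(x, grp)
  ld <- MASS::lda(x, grouping = grp)$scaling[, 1]
  cosang <- abs(sum(f$vectors[, 1] * ld)) /
    sqrt(sum(f$vectors[, 1]^2) * sum(ld^2))
  expect_gt(cosang, 0.99)
  # ordering: the first vector carries the largest between-group fraction
  expect_true(all(f$between_fraction[1] >= f$between_fraction))
  # identical groups: leading eigenvalue near zero
  f0 <- cva(rbind(x[grp == "a", ], x[grp == "a", ]),
            rep(c("a", "b"), each = 200))
  expect_lt(f0$eigenvalues[1], 0.05)
})

test_that("Mahalanobis table matches hand linear algebra on a 3-group toy", {
  # groups with known means and pooled covariance computable by hand
  xa <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))       # mean (1,1)
  xb <- xa + 4                                          # mean (5,5)
  xc <- sweep(xa, 2, c(8, 0), `+`)                      # mean (9,1)
  x <- rbind(xa, xb, xc)
  lb <- rep(c("a", "b", "c"), each = 4)
  D <- mahalanobis_pairwise(x, lb)
  # within SSCP: deviations (+-1, +-1) give diag(4,4) per group, so the
  # pooled covariance is diag(12,12)/(12 - 3) = (4/3) I
  S <- diag(2) * 4 / 3
  dm <- c(4, 4)
  expect_equal(D["a", "b"], sqrt(drop(t(dm) %*% solve(S) %*% dm)),
               tolerance = 1e-9)                       # sqrt(24)
  expect_equal(D["b", "c"], sqrt(24), tolerance = 1e-9)  # means differ (-4, 4)
  expect_equal(D["a", "c"], sqrt(48), tolerance = 1e-9)  # means differ (8, 0)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  # identity covariance reduces to the Euclidean distance of means
  set.seed(1)
  big <- matrix(rnorm(4000 * 2), 4000, 2)
  lb2 <- rep(c("p", "q"), each = 2000)
  big[lb2 == "q", ] <- big[lb2 == "q", ] + 3
  D2 <- mahalanobis_pairwise(big, lb2)
  expect_equal(D2["p", "q"], sqrt(18), tolerance = 0.1)
})

test_that("single-linkage clustering of group means matches the oracle", {
  # collinear means at 0, 1, 10: first merge joins {0, 1}
  x <- matrix(c(rep(0, 5), rep(1, 5), rep(10, 5)), ncol = 1)
  lb <- rep(c("g0", "g1", "g10"), each = 5)
  hc <- hcluster_group_means(x, lb)
  expect_equal(hc$height[1], 1)
  expect_true(all(diff(hc$height) >= 0))
  # 5-group toy equals brute-force single-linkage heights
  set.seed(9)
  gm <- matrix(rnorm(10), 5, 2) * 4
  xx <- do.call(rbind, lapply(1:5, function(i)
    sweep(matrix(rnorm(20 * 2, 0, 1e-6), 20, 2), 2, gm[i, ], `+`)))
  hc2 <- hcluster_group_means(xx, rep(1:5, each = 20))
  oracle <- hclust(dist(gm), method = "single")
  expect_equal(hc2$height, oracle$height, tolerance = 1e-4)
})

test_that("Wilks MANOVA: identity case, power and type-I error", {
  set.seed(13)
  x <- matrix(rnorm(90 * 3), 90, 3)
  lb <- rep(1:3, each = 30)
  # identical group means (same data relabeled): Lambda = 1
  x0 <- rbind(x[1:30, ], x[1:30, ], x[1:30, ])
  w0 <- manova_wilks(x0, lb)
  expect_gt(w0$wilks_lambda, 0.999)
  # strongly separated groups: Lambda near 0, tiny p
  xs <- x; xs[lb == 2, 1] <- xs[lb == 2, 1] + 10
  xs[lb == 3, 2] <- xs[lb == 3, 2] + 10
  ws <- manova_wilks(xs, lb)
  expect_lt(ws$wilks_lambda, 0.05)
  expect_lt(ws$p_value, 1e-6)
  # cross-check Lambda against R's manova
  fit <- summary(manova(xs ~ factor(lb)), test = "Wilks")
  expect_equal(ws$wilks_lambda, fit$stats[1, "Wilks"], tolerance = 1e-8)
  # null calibration: ~5% rejections over 500 label permutations
  rej <- 0
  for (i in 1:500) {
    lbp <- sample(lb)
    if (manova_wilks(x, lbp)$p_value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("KS test matches the asymptotic critical-value formula", {
  set.seed(14)
  x <- rnorm(100); y <- rnorm(100)
  k <- ks_two_sample(x, y)
  expect_equal(k$critical, 1.358 * sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(rnorm(50), rnorm(50) + 100)$D, 1)
  expect_true(ks_two_sample(rnorm(200), rnorm(200) + 2)$reject)
  expect_error(ks_two_sample(rnorm(5), rnorm(50)), "10")
})

test_that("Gaussian KDE normalizes and is consistent", {
  set.seed(15)
  k1 <- kde_gaussian(0.7, bandwidth = 0.5)
  expect_equal(k1$y[which.max(k1$y)], dnorm(0, 0, 0.5), tolerance = 1e-3)
  expect_equal(k1$x[which.max(k1$y)], 0.7, tolerance = 0.01)
  x <- rnorm(50000)
  kd <- kde_gaussian(x, bandwidth = 0.15)
  integral <- sum(kd$y) * diff(kd$x[1:2])
  expect_equal(integral, 1, tolerance = 1e-6)
  grid <- seq(-3, 3, 0.05)
  expect_lt(max(abs(kd$fun(grid) - dnorm(grid))), 0.02)
  expect_error(kde_gaussian(x, bandwidth = 0), "bandwidth")
})
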