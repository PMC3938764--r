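# Simulated panel where a known subset of organizational features drives
# speed; used by both ranking methods.
speed_panel <- function(seed, n = 1200, n_features = 30, drivers = 1:3,
                        coefs = c(0.9, -0.8, 0.7)) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_features), n, n_features)
  colnames(x) <- sprintf("ORG%02d", seq_len(n_features))
  ics <- drop(x[, drivers, drop = FALSE] %*% coefs[seq_along(drivers)]) +
    rnorm(n, 0, 1)
  p <- as_panel(as.data.frame(x, check.names = FALSE))
  p[["Instantaneous Cell Speed"]] <- ics
  p
}

test_that("CVA quintile ranking puts the speed driver first", {
  p <- speed_panel(1, drivers = 1, coefs = 1.5)
  r <- cva_rank_features(p)
  expect_equal(r$ranking$feature[1], "ORG01")
  # quintile boundaries at 20% / 80% exactly
  ics <- p[["Instantaneous Cell Speed"]]
  q <- quantile(ics, c(0.2, 0.8))
  expect_equal(r$n_slow, sum(ics <= q[1]))
  expect_equal(r$n_fast, sum(ics > q[2]))
  # two groups: the single canonical vector carries all between-group variation
  expect_equal(r$cv1_between_fraction, 1)
})

test_that("speed-independent features rank below the top decile", {
  hits <- 0
  for (seed in 1:20) {
    p <- speed_panel(seed + 100, n = 600, n_features = 20, drivers = 1:3)
    r <- cva_rank_features(p)
    pos <- match("ORG10", r$ranking$feature)   # a null feature
    if (pos > 2) hits <- hits + 1              # top decile of 20 = top 2
  }
  expect_gte(hits, 18)   # >= 90% of seeds
})

test_that("elastic-net path: shrinkage limits, OLS limit and optimum", {
  p <- speed_panel(3, n = 800, n_features = 10)
  en <- elastic_net_rank(p)
  # penalty -> infinity: all coefficients zero at the path start
  expect_equal(en$path$n_nonzero[1], 0)
  # adjusted R2 at the optimum >= both path endpoints
  expect_gte(en$path$adj_r2[en$opt_iteration], en$path$adj_r2[1])
  expect_gte(en$path$adj_r2[en$opt_iteration],
             en$path$adj_r2[nrow(en$path)])
  # near-zero penalty with n >> p approaches the OLS solution
  feats <- sprintf("ORG%02d", 1:10)
  ols <- coef(lm(p[["Instantaneous Cell Speed"]] ~
                   as.matrix(p[, feats])))[-1]
  en_last <- en$coefficients[, ncol(en$coefficients)]
  expect_lt(max(abs(en_last - ols)), 0.02)
  # the true drivers carry the largest coefficients at the optimum
  expect_setequal(en$ranking$feature[1:3], c("ORG01", "ORG02", "ORG03"))
})

test_that("elastic net shares coefficients across duplicated predictors", {
  set.seed(4)
  n <- 600
  x1 <- rnorm(n)
  p <- as_panel(a = x1, a_dup = x1 + rnorm(n, 0, 1e-6), b = rnorm(n))
  p[["Instantaneous Cell Speed"]] <- x1 + rnorm(n, 0, 0.5)
  en <- elastic_net_rank(p)
  co <- en$coefficients[, en$opt_iteration]
  expect_gt(abs(co["a"]), 0)
  # grouping effect: near-identical predictors get near-equal coefficients
  expect_lt(abs(co["a"] - co["a_dup"]) / max(abs(co["a"]), 1e-12), 0.05)
})

test_that("Spearman matrix equals the rank-then-Pearson oracle", {
  set.seed(7)
  x <- matrix(rnorm(200 * 5), 200, 5)
  x[, 2] <- exp(x[, 1])          # monotone transform: rs exactly 1
  p <- as_panel(as.data.frame(x, check.names = FALSE))
  feats <- names(p)[-(1:4)]
  rs <- spearman_matrix(p, features = feats)
  expect_true(isSymmetric(unclass(rs)))
  expect_equal(unname(diag(rs)), rep(1, 5))
  expect_equal(rs[1, 2], 1)
  oracle <- cor(apply(x, 2, rank))
  expect_equal(unname(rs), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant features are missing-flagged
  p$const <- 1
  rs2 <- spearman_matrix(p, features = c(feats, "const"))
  expect_true(all(is.na(rs2["const", setdiff(colnames(rs2), "const")])))
  expect_equal(attr(rs2, "constant_features"), "const")
  # ranked scatter table
  rp <- ranked_pair(p, feats[1], feats[2])
  expect_equal(cor(rp$rank_f1, rp$rank_f2), rs[1, 2], tolerance = 1e-12)
})

test_that("CVA and EN top lists jointly recover planted drivers", {
  p <- speed_panel(11, n = 1500, n_features = 30, drivers = 1:3)
  cv <- cva_rank_features(p)
  en <- elastic_net_rank(p)
  top_cv <- cv$ranking$feature[1:15]
  top_en <- en$ranking$feature[1:15]
  truth <- c("ORG01", "ORG02", "ORG03")
  expect_true(all(truth %in% top_cv))
  expect_true(all(truth %in% top_en))
  overlap <- intersect(top_cv, top_en)
  expect_gt(mean(truth %in% overlap), 0.5)   # majority of drivers overlap
})
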