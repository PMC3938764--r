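test_that("lagged designs have the counted rows and never mix tracks", {
  p1 <- ar1_panel(c("Y", "X"), n_cells = 1, track_length = 20, seed = 1)
  d <- build_lagged_design(p1, "Y", "X", p_y = 3, p_x = 3)
  expect_equal(d$n, 17)                      # T - max(p_y, p_x)
  expect_equal(colnames(d$X),
               c("intercept", paste0("y_lag", 1:3), paste0("x_lag", 1:3)))
  p2 <- rbind(ar1_panel(c("Y", "X"), 1, 20, seed = 1),
              within(ar1_panel(c("Y", "X"), 1, 10, seed = 2),
                     cell_id <- 2L))
  d2 <- build_lagged_design(p2, "Y", "X", 3, 3)
  expect_equal(d2$n, 17 + 7)
  expect_equal(as.vector(table(d2$track)), c(17, 7))
})

test_that("lag columns equal a hand-built matrix on a tiny track", {
  y <- c(1, 2, 4, 7, 11)
  x <- c(0, 1, 0, 1, 0)
  p <- data.frame(condition = "c", repeat_id = 1L, cell_id = 1L,
                  frame = 0:4, Y = y, X = x)
  lm_obj <- cellwiring:::.lag_matrix(p, "Y", "X", 2)
  d <- cellwiring:::.design_at(lm_obj, 2, 1)
  # T - max(p_y, p_x) = 3 rows, at t = 2, 3, 4 (0-based)
  hand <- cbind(intercept = 1, y_lag1 = c(2, 4, 7), y_lag2 = c(1, 2, 4),
                x_lag1 = c(1, 0, 1))
  expect_equal(unname(d$X), unname(hand))
  expect_equal(d$y, c(4, 7, 11))
  # the public constructor refuses designs with too few rows
  expect_error(build_lagged_design(p, "Y", "X", p_y = 2, p_x = 1),
               "refused")
})

test_that("pooled OLS reproduces exact models and the normal equations", {
  # noiseless AR(1): coefficient and R2 exact
  y <- numeric(40); y[1] <- 1
  for (t in 2:40) y[t] <- 0.5 * y[t - 1] + 0.1
  p <- data.frame(condition = "c", repeat_id = 1L, cell_id = 1L,
                  frame = 0:39, Y = y, X = rnorm(40))
  d <- build_lagged_design(p, "Y", "X", p_y = 1, p_x = 0)
  f <- fit_pooled_ar(d)
  expect_equal(unname(f$coefficients["y_lag1"]), 0.5, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # small design vs normal-equations hand solve
  set.seed(5)
  p2 <- ar1_panel(c("Y", "X"), 3, 15, seed = 5)
  d2 <- build_lagged_design(p2, "Y", "X", 2, 2)
  f2 <- fit_pooled_ar(d2)
  beta <- solve(crossprod(d2$X), crossprod(d2$X, d2$y))
  expect_equal(unname(f2$coefficients), as.vector(beta), tolerance = 1e-10)
  # adding a regressor never lowers unadjusted R2
  d1 <- build_lagged_design(p2, "Y", "X", 2, 0)
  d1$X <- d2$X[, 1:3]; d1$y <- d2$y; d1$n <- d2$n  # same rows, fewer columns
  expect_lte(fit_pooled_ar(d1)$r2, f2$r2 + 1e-12)
  # rank deficiency refused
  d3 <- d2; d3$X <- cbind(d2$X, dup = d2$X[, 2])
  expect_error(fit_pooled_ar(d3), "rank-deficient")
})

test_that("Granger-Sargent statistic matches hand arithmetic and limits", {
  gs <- granger_sargent(120, 100, p_x = 2, p_y = 2, n = 105)
  expect_equal(gs$statistic, 10)                     # (20/2)/(100/100)
  expect_equal(gs$p_value, pf(10, 2, 100, lower.tail = FALSE))
  # no improvement: statistic 0, p = 1
  g0 <- granger_sargent(50, 50, 1, 1, 100)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)
  # chi-square form
  gc <- granger_sargent(120, 100, 2, 2, 105, form = "chisq")
  expect_equal(gc$statistic, 105 * 20 / 100)
  expect_error(granger_sargent(10, 0, 1, 1, 50), "positive")
})

test_that("Granger-Sargent p-values match a brute-force nested-OLS oracle", {
  # independent implementation: R's lm + anova on explicit lag frames
  set.seed(42)
  max_dp <- 0
  for (i in 1:50) {
    n_cells <- sample(3:6, 1)
    len <- sample(12:20, 1)
    p_y <- sample(1:3, 1); p_x <- sample(1:3, 1)
    panel <- ar1_panel(c("Y", "X"), n_cells, len, seed = 1000 + i)
    pair <- lag_model_pair(panel, "Y", "X", p_y, p_x)
    got <- granger_sargent_test(pair)$p_value
    # oracle: build lag frames track by track with embed(), fit with lm()
    frames <- do.call(rbind, lapply(split(panel, panel$cell_id), function(tr) {
      tr <- tr[order(tr$frame), ]
      m <- max(p_y, p_x)
      if (nrow(tr) <= m) return(NULL)
      ey <- embed(tr$Y, m + 1)
      ex <- embed(tr$X, m + 1)
      data.frame(y = ey[, 1], ey[, 1 + seq_len(p_y), drop = FALSE],
                 ex[, 1 + seq_len(p_x), drop = FALSE])
    }))
    names(frames) <- c("y", paste0("yl", seq_len(p_y)),
                       paste0("xl", seq_len(p_x)))
    fa <- lm(y ~ ., data = frames[, c("y", paste0("yl", seq_len(p_y)))])
    fb <- lm(y ~ ., data = frames)
    oracle <- anova(fa, fb)$`Pr(>F)`[2]
    max_dp <- max(max_dp, abs(got - oracle))
  }
  expect_lt(max_dp, 1e-8)
})

test_that("lag surfaces have the pinned shape and nesting behavior", {
  sim <- simulate_var_panel(coupled_var_spec(-0.6), 40, 40, seed = 6)
  s <- r2_surface(sim$panel, "F2", "F1", L_max = 10)
  expect_equal(dim(s$adj_r2), c(10, 10))
  expect_length(s$y_only, 10)
  # with strong coupling, adding X lags beats the response-only model
  expect_gt(s$adj_r2[1, 1], s$y_only[1])
})

test_that("significance grids carry consistent bins, signs and ACF", {
  sim <- simulate_var_panel(coupled_var_spec(-0.5), 60, 40, seed = 8)
  g <- significance_grid(sim$panel, "F2", "F1", L_max = 10)
  expect_equal(dim(g$p), c(10, 10))
  # bins consistent with p-values
  expect_equal(g$bin, matrix(cellwiring:::.bin_p(g$p), 10, 10,
                             dimnames = dimnames(g$bin)))
  expect_equal(cellwiring:::.bin_p(c(0.02, 5e-4, 0.2, 5e-3, 5e-5)),
               c("<0.05", "<0.001", "ns", "<0.01", "<0.0001"))
  # negative coupling: significant cells carry sign "-"
  expect_true(all(g$sign[g$p < 0.05] == "-"))
  # autocorrelation at lag 0 is exactly 1
  expect_equal(g$autocorrelation[1], 1)
  expect_length(g$autocorrelation, 11)
})

test_that("statistics are invariant to cell relabeling and row order", {
  sim <- simulate_var_panel(coupled_var_spec(-0.5), 20, 30, seed = 9)
  g1 <- significance_grid(sim$panel, "F2", "F1", L_max = 5)
  shuf <- sim$panel[sample(nrow(sim$panel)), ]
  shuf$cell_id <- max(shuf$cell_id) + 1 - shuf$cell_id   # relabel
  g2 <- significance_grid(shuf, "F2", "F1", L_max = 5)
  expect_equal(g1$p, g2$p, tolerance = 1e-12)
  expect_equal(g1$adj_r2, g2$adj_r2, tolerance = 1e-12)
})
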