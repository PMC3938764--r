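test_that("non-stationary VAR specs are rejected with the spectral radius", {
  sp <- var_spec(2, coupling = array(c(1.05, 0, 0, 0.5), c(1, 2, 2)))
  expect_gt(var_spectral_radius(sp), 1)
  expect_error(simulate_var_panel(sp, 5, 20, seed = 1), "spectral radius")
  expect_error(var_spec(1, noise_sd = 0), "positive")
})

test_that("zero coupling gives uncorrelated lagged features", {
  sp <- var_spec(2, coupling = array(0, c(1, 2, 2)))
  sim <- simulate_var_panel(sp, n_cells = 60, track_length = 40, seed = 7)
  expect_equal(nrow(sim$truth$edges), 0)
  lm1 <- cellwiring:::.lag_matrix(sim$panel, "F2", "F1", 1)
  ok <- !is.na(lm1$xlags[, 1])
  r <- cor(lm1$xlags[ok, 1], lm1$y[ok])
  expect_lt(abs(r), 3 / sqrt(sum(ok)))
})

test_that("stationary VAR panels reject the unit root for nearly all tracks", {
  sp <- var_spec(2, coupling = array(c(0.6, 0, 0, 0.6), c(1, 2, 2)))
  sim <- simulate_var_panel(sp, n_cells = 200, track_length = 60, seed = 5)
  st <- check_stationarity(sim$panel, features = c("F1", "F2"))
  expect_true(all(st$verdict == "stationary"))
  expect_true(all(st$fraction_rejecting >= 0.85))
})

test_that("negative lagged coupling propagates a negative sign in every seed", {
  for (seed in 1:10) {
    sim <- simulate_var_panel(coupled_var_spec(-0.5), n_cells = 40,
                              track_length = 40, seed = seed)
    lm1 <- cellwiring:::.lag_matrix(sim$panel, "F2", "F1", 1)
    ok <- !is.na(lm1$xlags[, 1])
    expect_lt(cor(lm1$xlags[ok, 1], lm1$y[ok]), 0)
  }
  # ground truth lists exactly the nonzero cross-couplings with signs
  tr <- simulate_var_panel(coupled_var_spec(-0.5), 5, 20, seed = 1)$truth
  expect_equal(tr$edges$source, "F1")
  expect_equal(tr$edges$target, "F2")
  expect_equal(tr$edges$sign, "-")
})

test_that("seeded VAR runs are bit-reproducible", {
  a <- simulate_var_panel(coupled_var_spec(), 5, 25, seed = 3)$panel
  b <- simulate_var_panel(coupled_var_spec(), 5, 25, seed = 3)$panel
  expect_identical(a, b)
})

test_that("microscopy simulator produces the requested bookkeeping", {
  sim <- small_dataset()
  ds <- sim$dataset
  ids <- unique(ds$cells[, c("condition", "repeat_id", "cell_id")])
  expect_equal(nrow(ids), 4)
  lens <- table(ds$cells$cell_id)
  expect_true(all(lens <= 15))
  # all generated CMAC areas exceed the segmentation floor
  expect_true(all(ds$cmacs$area_um2 > 0.05))
  expect_true(all(ds$cmacs$minor_axis_um > 0))
  # pixel strings decode to >= 8 paired values
  np <- lengths(cellwiring:::.parse_pixels(ds$cmacs$ch1_pixels))
  expect_true(all(np >= 8))
  expect_equal(np, lengths(cellwiring:::.parse_pixels(ds$cmacs$ch2_pixels)))
})

test_that("coupling edges must name actuatable catalog features", {
  expect_error(microscopy_sim_spec(coupling_edges = list(
    list(source = "No Such Feature", target = "Instantaneous Cell Speed",
         lag = 1, coefficient = 0.5))), "unknown feature")
  expect_error(microscopy_sim_spec(coupling_edges = list(
    list(source = "Cell Perimeter", target = "Instantaneous Cell Speed",
         lag = 1, coefficient = 0.5))), "not actuatable")
})

test_that("microscopy runs are seed-reproducible and truth echoes couplings", {
  spec <- microscopy_sim_spec(n_cells = 2, n_frames = 10,
                              coupling_edges = list(
                                list(source = "Mean [CMAC Area] per Cell",
                                     target = "Instantaneous Cell Speed",
                                     lag = 2, coefficient = -0.6)))
  a <- simulate_microscopy_panel(spec, seed = 9)
  b <- simulate_microscopy_panel(spec, seed = 9)
  expect_identical(a$dataset$cmacs, b$dataset$cmacs)
  expect_equal(a$truth$edges$lag, 2L)
  expect_equal(a$truth$edges$sign, "-")
})

test_that("entry/exit truncation is bounded, seeded and contiguous", {
  sim <- small_dataset()
  ds <- sim$dataset
  expect_error(inject_missingness(ds, 1.2), "probability")
  expect_identical(inject_missingness(ds, 0), ds)
  t1 <- inject_missingness(ds, 0.8, seed = 4)
  t2 <- inject_missingness(ds, 0.8, seed = 4)
  expect_identical(t1$cells, t2$cells)
  key <- paste(t1$cells$cell_id)
  for (k in unique(key)) {
    fr <- sort(t1$cells$frame[key == k])
    expect_gte(length(fr), 2)              # never shorter than 2 frames
    if (length(fr) > 1) expect_true(all(diff(fr) == 1))  # no interior gaps
  }
  # truncation only removes frames, never reorders or edits them
  expect_true(nrow(t1$cells) < nrow(ds$cells))
})
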