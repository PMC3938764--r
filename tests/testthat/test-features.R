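# Builders for minimal object tables with fully known geometry/intensities.
square_cell <- function(frames, cx = 0, cy = 0, half = 10) {
  do.call(rbind, lapply(seq_along(frames), function(i) data.frame(
    condition = "c", repeat_id = 1L, cell_id = 1L, frame = frames[i],
    centroid_x_um = cx[pmin(i, length(cx))], centroid_y_um = cy[pmin(i, length(cy))],
    polygon_wkt = polygon_to_wkt(cbind(
      cx[pmin(i, length(cx))] + c(-half, half, half, -half),
      cy[pmin(i, length(cy))] + c(-half, -half, half, half))))))
}

mk_cmac <- function(cmac_id, frames, x, y, area = 1, px1 = "1;2;3;4;5;6;7;8",
                    px2 = "1;2;3;4;5;6;7;8", bg = 0) {
  data.frame(condition = "c", repeat_id = 1L, cell_id = 1L, cmac_id = cmac_id,
             frame = frames, centroid_x_um = x, centroid_y_um = y,
             area_um2 = area, major_axis_um = 1.2, minor_axis_um = 0.8,
             ch1_pixels = px1, ch2_pixels = px2, ch1_bg = bg, ch2_bg = bg)
}

empty_cmac_features <- function()
  data.frame(condition = character(0), repeat_id = integer(0),
             cell_id = integer(0), frame = integer(0))

test_that("per-CMAC features cover the catalog and known geometry", {
  cells <- square_cell(0:5)
  cm <- rbind(mk_cmac(1, 0:5, 0, 0),            # at the cell centroid
              mk_cmac(2, 0:5, 10, 0),           # on the boundary
              mk_cmac(3, 2:4, 3, 3))
  cm <- correct_local_background(cm)
  pr <- parse_cmac_tracks(cm, first_frame = 0, last_frame = 5)
  cf <- compute_cmac_features(pr$cmacs, cells)
  expect_equal(setdiff(names(cf), c("condition", "repeat_id", "cell_id",
                                    "cmac_id", "frame", "censored_start",
                                    "censored_end")),
               cmac_feature_catalog()$name)
  s <- cf[["Standardized CMAC Distance to Cell Edge"]]
  expect_equal(unique(s[cf$cmac_id == 1]), 1)   # |P - C| = 0
  expect_equal(unique(s[cf$cmac_id == 2]), 0)   # on the boundary
  # identical pixel vectors: colocalization +1; negated: -1
  expect_equal(unique(cf[["EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC"]][
    cf$cmac_id == 1]), 1)
  cm2 <- correct_local_background(
    mk_cmac(9, 0:2, 0, 0, px2 = "8;7;6;5;4;3;2;1"))
  pr2 <- parse_cmac_tracks(cm2, first_frame = -5, last_frame = 99)
  cf2 <- compute_cmac_features(pr2$cmacs, square_cell(0:2))
  expect_equal(unique(cf2[["EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC"]]),
               -1)
  # constant pixel vector: colocalization undefined -> missing
  cm3 <- correct_local_background(
    mk_cmac(8, 0:2, 0, 0, px1 = "5;5;5;5;5;5;5;5"))
  pr3 <- parse_cmac_tracks(cm3, first_frame = -5, last_frame = 99)
  cf3 <- compute_cmac_features(pr3$cmacs, square_cell(0:2))
  expect_true(all(is.na(
    cf3[["EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC"]])))
  # interior track (frames 2:4) is uncensored; lifetime = 3 frames x 5 min
  expect_equal(unique(cf[["CMAC Lifetime"]][cf$cmac_id == 3]), 15)
  # censored tracks carry missing lifetime
  expect_true(all(is.na(cf[["CMAC Lifetime"]][cf$cmac_id == 1])))
})

test_that("corrected totals recover a generator-known signal", {
  true_mean <- 7.5; bg <- 3.25; area <- 0.4
  px <- paste(rep(true_mean + bg, 10), collapse = ";")
  cm <- correct_local_background(
    mk_cmac(1, 0:2, 0, 0, area = area, px1 = px, px2 = px, bg = bg))
  expect_equal(cm$ch1_total_corr, rep(true_mean * area, 3), tolerance = 1e-9)
})

test_that("cell features: schema count, compactness and speed arithmetic", {
  cells <- square_cell(0:9, cx = seq(0, 9))   # 1 um per 5-min frame
  panel <- compute_cell_features(cells, empty_cmac_features(),
                                 smooth = FALSE)
  expect_equal(ncol(panel) - 4, 88)
  expect_equal(names(panel)[-(1:4)], cell_feature_catalog()$name)
  # unit square scaled: compactness P^2/(4 pi A) = 4/pi regardless of size
  expect_equal(unique(panel[["Cell Compactness"]]), 4 / pi, tolerance = 1e-9)
  expect_equal(panel[["Cell Area"]][1], 400)
  expect_equal(panel[["Cell Perimeter"]][1], 80)
  # straight line at 1 um/frame, smoothing off: ICS = 0.2 um/min
  expect_true(is.na(panel[["Instantaneous Cell Speed"]][1]))
  expect_equal(panel[["Instantaneous Cell Speed"]][-1], rep(0.2, 9),
               tolerance = 1e-9)
  # zero CMACs: aggregates missing, cell-scale features still computed
  expect_true(all(is.na(panel[["Median [CMAC Area] per Cell"]])))
  expect_equal(unique(panel[["Number of CMACs per Cell"]]), 0)
})

test_that("constant CMAC populations give zero spread aggregates", {
  cells <- square_cell(0:3)
  cm <- do.call(rbind, lapply(1:5, function(i)
    mk_cmac(i, 0:3, i / 2 - 1, 0, area = 0.8)))
  cm <- correct_local_background(cm)
  pr <- parse_cmac_tracks(cm, first_frame = -9, last_frame = 99)
  cf <- compute_cmac_features(pr$cmacs, cells)
  panel <- compute_cell_features(cells, cf, smooth = FALSE)
  expect_equal(unique(panel[["SD [CMAC Area] per Cell"]]), 0)
  expect_equal(unique(panel[["IDR [CMAC Area] per Cell"]]), 0)
  expect_equal(unique(panel[["Mean [CMAC Area] per Cell"]]), 0.8)
  expect_equal(unique(panel[["Sum [CMAC Area] per Cell"]]), 4)
  expect_equal(unique(panel[["Number of CMACs per Cell"]]), 5)
})

test_that("lifetime aggregates never include censored CMAC tracks", {
  cells <- square_cell(0:10)
  cm <- rbind(mk_cmac(1, 0:4, 1, 1),    # censored at sequence start
              mk_cmac(2, 3:6, 2, 2),    # complete: 4 frames = 20 min
              mk_cmac(3, 5:8, 3, 3))    # complete: 4 frames = 20 min
  cm <- correct_local_background(cm)
  pr <- parse_cmac_tracks(cm, first_frame = 0, last_frame = 10)
  cf <- compute_cmac_features(pr$cmacs, cells)
  panel <- compute_cell_features(cells, cf, smooth = FALSE)
  # frame 3: CMACs 1 (censored) and 2 (complete) present
  expect_equal(panel[["Mean [CMAC Lifetime] per Cell"]][panel$frame == 3], 20)
  # frame 0: only the censored CMAC: aggregate missing
  expect_true(is.na(panel[["Mean [CMAC Lifetime] per Cell"]][panel$frame == 0]))
})

test_that("spline smoothing improves speed recovery on noisy trajectories", {
  wins <- 0
  for (seed in 1:50) {
    set.seed(seed)
    n <- 40
    truth <- seq(0, n - 1)          # 1 um/frame true motion
    noisy_x <- truth + rnorm(n, 0, 0.3)
    noisy_y <- rnorm(n, 0, 0.3)
    cells <- square_cell(0:(n - 1), cx = noisy_x, cy = noisy_y)
    raw <- compute_cell_features(cells, empty_cmac_features(),
                                 smooth = FALSE)[["Instantaneous Cell Speed"]]
    sm <- compute_cell_features(cells, empty_cmac_features(),
                                smooth = TRUE)[["Instantaneous Cell Speed"]]
    err_raw <- mean(abs(raw - 0.2), na.rm = TRUE)
    err_sm <- mean(abs(sm - 0.2), na.rm = TRUE)
    if (err_sm < err_raw) wins <- wins + 1
  }
  expect_gte(wins, 45)   # >= 90% of seeds
})
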