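# Feature extraction: 29 instantaneous per-CMAC features, then the 88
# single-cell features (6 cell-morphology + CMAC count + 80 population
# aggregates + Instantaneous Cell Speed).

.track_key <- function(d, cols = c("condition", "repeat_id", "cell_id"))
  do.call(paste, c(d[cols], sep = "\r"))

#' Compute the 29 instantaneous CMAC features
#'
#' Input records must be parsed ([parse_cmac_tracks()]) and
#' background-corrected ([correct_local_background()]; optionally
#' standardized). Localization features are computed against the parent
#' cell outline of the same frame; colocalization is the Pearson
#' correlation of the paired per-pixel channel intensities (undefined, and
#' flagged missing, when a pixel vector is constant).
#'
#' @param cmacs Parsed, corrected CMAC records.
#' @param cells Cell table with `polygon_wkt` per (condition, repeat_id,
#'   cell_id, frame).
#' @param frame_interval Minutes per frame (default 5).
#' @return Data frame: key columns (`condition`, `repeat_id`, `cell_id`,
#'   `cmac_id`, `frame`, `censored_start`, `censored_end`) plus the 29
#'   feature columns named as in [cmac_feature_catalog()].
#' @export
compute_cmac_features <- function(cmacs, cells, frame_interval = 5) {
  stopifnot(nrow(cmacs) > 0)
  if (!all(c("censored_start", "censored_end") %in% names(cmacs)))
    stop("run parse_cmac_tracks() first")
  if (!"ch1_mean_corr" %in% names(cmacs))
    stop("run correct_local_background() first")
  key <- paste(.track_key(cmacs), cmacs$cmac_id, sep = "\r")
  ord <- order(key, cmacs$frame)
  cmacs <- cmacs[ord, , drop = FALSE]
  key <- key[ord]
  out <- cmacs[, c("condition", "repeat_id", "cell_id", "cmac_id", "frame",
                   "censored_start", "censored_end")]
  F <- list()
  F[["CMAC Area"]] <- cmacs$area_um2
  F[["CMAC Major Axis"]] <- cmacs$major_axis_um
  F[["CMAC Minor Axis"]] <- cmacs$minor_axis_um
  F[["CMAC Axis Ratio"]] <- cmacs$major_axis_um / cmacs$minor_axis_um
  F[["CMAC Eccentricity"]] <-
    sqrt(pmax(0, 1 - (cmacs$minor_axis_um / cmacs$major_axis_um)^2))
  F[["CMAC Form Factor"]] <-
    4 * cmacs$area_um2 / (pi * cmacs$major_axis_um * cmacs$minor_axis_um)

  first_of_track <- !duplicated(key)
  dx <- c(NA, diff(cmacs$centroid_x_um))
  dy <- c(NA, diff(cmacs$centroid_y_um))
  disp <- sqrt(dx^2 + dy^2)
  disp[first_of_track] <- NA
  F[["CMAC Displacement"]] <- disp
  F[["CMAC Sliding Speed"]] <- disp / frame_interval
  cum <- stats::ave(ifelse(is.na(disp), 0, disp), key, FUN = cumsum)
  cum[first_of_track] <- 0
  F[["CMAC Cumulative Displacement"]] <- cum
  tmin <- stats::ave(cmacs$frame, key, FUN = min)
  tmax <- stats::ave(cmacs$frame, key, FUN = max)
  F[["CMAC Lifetime to Date"]] <- (cmacs$frame - tmin + 1) * frame_interval
  life <- (tmax - tmin + 1) * frame_interval
  life[cmacs$censored_start | cmacs$censored_end] <- NA  # incomplete lifetime
  F[["CMAC Lifetime"]] <- life
  F[["CMAC Age Fraction"]] <- F[["CMAC Lifetime to Date"]] / life

  chg <- function(v) { d <- c(NA, diff(v)); d[first_of_track] <- NA; d }
  F[["Change in CMAC Total EGFP-Paxillin Intensity"]] <- chg(cmacs$ch1_total_corr)
  F[["Change in CMAC Total RubyRed-LifeAct Intensity"]] <- chg(cmacs$ch2_total_corr)
  F[["Change in CMAC Area"]] <- chg(cmacs$area_um2)

  F[["CMAC Mean EGFP-Paxillin Intensity"]] <- cmacs$ch1_mean_corr
  F[["CMAC Total EGFP-Paxillin Intensity"]] <- cmacs$ch1_total_corr
  F[["CMAC Mean RubyRed-LifeAct Intensity"]] <- cmacs$ch2_mean_corr
  F[["CMAC Total RubyRed-LifeAct Intensity"]] <- cmacs$ch2_total_corr
  F[["CMAC Raw Mean EGFP-Paxillin Intensity"]] <- cmacs$ch1_mean_raw
  F[["CMAC Raw Mean RubyRed-LifeAct Intensity"]] <- cmacs$ch2_mean_raw
  F[["CMAC EGFP-Paxillin Background Intensity"]] <- cmacs$ch1_bg
  F[["CMAC RubyRed-LifeAct Background Intensity"]] <- cmacs$ch2_bg
  ratio <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  F[["CMAC Paxillin-LifeAct Mean Intensity Ratio"]] <-
    ratio(cmacs$ch1_mean_corr, cmacs$ch2_mean_corr)
  F[["CMAC Paxillin-LifeAct Total Intensity Ratio"]] <-
    ratio(cmacs$ch1_total_corr, cmacs$ch2_total_corr)

  # localization against the parent cell outline, per cell-frame
  cell_key <- paste(.track_key(cells), cells$frame, sep = "\r")
  poly_lookup <- stats::setNames(cells$polygon_wkt, cell_key)
  ckey <- paste(.track_key(cmacs), cmacs$frame, sep = "\r")
  s <- de <- dc <- rep(NA_real_, nrow(cmacs))
  ckey_groups <- split(seq_len(nrow(cmacs)), ckey)
  for (k in names(ckey_groups)) {
    wkt <- poly_lookup[k]
    if (is.na(wkt)) next
    poly <- wkt_to_polygon(wkt)
    idx <- ckey_groups[[k]]
    sed <- standardized_edge_distance(
      cbind(cmacs$centroid_x_um[idx], cmacs$centroid_y_um[idx]), poly)
    s[idx] <- sed$standardized; de[idx] <- sed$d_edge; dc[idx] <- sed$d_center
  }
  F[["Standardized CMAC Distance to Cell Edge"]] <- s
  F[["CMAC Distance to Cell Edge"]] <- de
  F[["CMAC Distance to Cell Center"]] <- dc

  p1 <- .parse_pixels(cmacs$ch1_pixels)
  p2 <- .parse_pixels(cmacs$ch2_pixels)
  F[["EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC"]] <-
    mapply(function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
      else stats::cor(a, b)
    }, p1, p2)

  stopifnot(identical(names(F), cmac_feature_catalog()$name))
  out <- cbind(out, as.data.frame(F, check.names = FALSE, optional = TRUE))
  names(out)[-(1:7)] <- names(F)
  rownames(out) <- NULL
  out
}

.idr <- function(x) unname(diff(stats::quantile(x, c(0.1, 0.9), type = 7)))

.aggregate_values <- function(v, agg) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  switch(agg,
         Mean = mean(v), Median = stats::median(v), Sum = sum(v),
         SD = if (length(v) > 1) stats::sd(v) else 0,
         IDR = .idr(v))
}

# GCV smoothing-spline trajectory; falls back to the raw positions when the
# track is too short to support spline fitting.
.smooth_trajectory <- function(t, x, y, spar = NULL) {
  if (length(t) < 8) return(list(x = x, y = y))
  fit1 <- try(stats::smooth.spline(t, x, spar = spar, cv = FALSE),
              silent = TRUE)
  fit2 <- try(stats::smooth.spline(t, y, spar = spar, cv = FALSE),
              silent = TRUE)
  if (inherits(fit1, "try-error") || inherits(fit2, "try-error"))
    return(list(x = x, y = y))
  list(x = stats::predict(fit1, t)$y, y = stats::predict(fit2, t)$y)
}

#' Compute the 88 single-cell features per frame
#'
#' Cell-scale morphology is computed from the polygon outline (Compactness
#' = P^2 / (4 pi A), >= 1, higher for less round cells; the axis features
#' come from the outline's second area moments). CMAC population aggregates
#' apply Mean, Median, Sum, SD and IDR (interdecile range, q90 - q10) to
#' the 16 base CMAC features over the CMACs present in that frame;
#' lifetime aggregates never include censored CMAC tracks (their lifetimes
#' are missing by construction). Instantaneous Cell Speed is the
#' displacement of the spline-smoothed centroid trajectory per frame
#' interval (um/min); the smoothing penalty is chosen by generalized
#' cross-validation unless `spar` is given.
#'
#' @param cells Cell table (`condition`, `repeat_id`, `cell_id`, `frame`,
#'   `centroid_x_um`, `centroid_y_um`, `polygon_wkt`).
#' @param cmac_features Output of [compute_cmac_features()].
#' @param frame_interval Minutes per frame.
#' @param smooth Smooth trajectories before differencing (default TRUE).
#' @param spar Optional fixed `smooth.spline` smoothing parameter.
#' @return Data frame: key columns plus the 88 feature columns named as in
#'   [cell_feature_catalog()]. A frame with zero CMACs keeps its
#'   cell-scale features; its CMAC aggregates are missing.
#' @export
compute_cell_features <- function(cells, cmac_features, frame_interval = 5,
                                  smooth = TRUE, spar = NULL) {
  stopifnot(nrow(cells) > 0)
  cat88 <- cell_feature_catalog()
  key <- .track_key(cells)
  ord <- order(key, cells$frame)
  cells <- cells[ord, , drop = FALSE]
  key <- key[ord]
  tracks <- split(seq_len(nrow(cells)), key)
  if (any(vapply(tracks, length, integer(1)) < 2))
    stop("every cell track needs >= 2 frames")
  n <- nrow(cells)
  out <- cells[, c("condition", "repeat_id", "cell_id", "frame")]
  # polygon morphology
  morph <- matrix(NA_real_, n, 6,
                  dimnames = list(NULL, c("Cell Area", "Cell Perimeter",
                                          "Cell Compactness", "Cell Major Axis",
                                          "Cell Minor Axis", "Cell Aspect Ratio")))
  for (i in seq_len(n)) {
    poly <- wkt_to_polygon(cells$polygon_wkt[i])
    pr <- polygon_properties(poly)
    ax <- .polygon_axes(poly)
    morph[i, ] <- c(pr$area, pr$perimeter,
                    pr$perimeter^2 / (4 * pi * pr$area),
                    ax$major, ax$minor, ax$major / ax$minor)
  }
  # instantaneous cell speed from (optionally smoothed) trajectories
  ics <- rep(NA_real_, n)
  for (idx in tracks) {
    tr <- if (smooth) .smooth_trajectory(cells$frame[idx],
                                         cells$centroid_x_um[idx],
                                         cells$centroid_y_um[idx], spar)
          else list(x = cells$centroid_x_um[idx], y = cells$centroid_y_um[idx])
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    ics[idx[-1]] <- d / (diff(cells$frame[idx]) * frame_interval)
  }
  # CMAC population aggregates
  agg_rows <- cat88[cat88$scale == "cmac_population", ]
  aggm <- matrix(NA_real_, n, nrow(agg_rows),
                 dimnames = list(NULL, agg_rows$name))
  ncmac <- rep(0, n)
  cf_key <- paste(.track_key(cmac_features), cmac_features$frame, sep = "\r")
  cell_frame_key <- paste(key, cells$frame, sep = "\r")
  cf_groups <- split(seq_len(nrow(cmac_features)), cf_key)
  for (i in seq_len(n)) {
    rows <- cf_groups[[cell_frame_key[i]]]
    if (is.null(rows)) next
    ncmac[i] <- length(rows)
    for (j in seq_len(nrow(agg_rows))) {
      vals <- cmac_features[[agg_rows$base[j]]][rows]
      aggm[i, j] <- .aggregate_values(vals, agg_rows$aggregator[j])
    }
  }
  feat <- cbind(as.data.frame(morph, check.names = FALSE),
                data.frame("Number of CMACs per Cell" = ncmac,
                           check.names = FALSE),
                as.data.frame(aggm, check.names = FALSE),
                data.frame("Instantaneous Cell Speed" = ics,
                           check.names = FALSE))
  feat <- feat[, cat88$name]
  stopifnot(ncol(feat) == 88)
  out <- cbind(out, feat)
  rownames(out) <- NULL
  out
}
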