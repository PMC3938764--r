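# Object-level microscopy simulator: tracked cells (polygon outlines,
# centroids) and their CMAC populations (birth/death, areas, axes, paired
# per-pixel channel intensities, local backgrounds), with configurable
# lagged causal couplings among named single-cell features. Couplings act on
# per-cell latent driver series and are rendered into the objects, so the
# downstream pipeline must recover them from extracted features.

# Feature -> render hook registry. Each driver modulates one generator dial.
.SIM_DRIVERS <- c(
  "Instantaneous Cell Speed",
  "Cell Compactness",
  "Cell Area",
  "Number of CMACs per Cell",
  "Mean [CMAC Area] per Cell",
  "Mean [CMAC Lifetime] per Cell",
  "Mean [CMAC Mean EGFP-Paxillin Intensity] per Cell",
  "Median [EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC] per Cell")

#' Specify a simulated live-cell imaging experiment
#'
#' Parameters mirror the imaging regime the pipeline targets: 5-min frame
#' interval, 0.21 um pixels, punctate CMACs segmented above 0.05 um2.
#' Causal structure is injected through `coupling_edges`: lagged linear
#' couplings among per-cell latent drivers of named single-cell features.
#'
#' @param n_cells Number of cells per condition.
#' @param n_frames Frames per track (>= 3).
#' @param frame_interval Minutes between frames (default 5).
#' @param pixel_size Pixel edge in um (default 0.21).
#' @param cmac_birth_rate Mean CMAC births per frame per cell at equilibrium
#'   deficit 1; together with the lifetime it sets the standing CMAC count.
#' @param cmac_lifetime Mean CMAC lifetime in frames (geometric lifetimes).
#' @param n_cmacs Target standing CMAC count per cell.
#' @param coupling_edges List of edges, each
#'   `list(source =, target =, lag =, coefficient =)`; source/target must be
#'   single-cell catalog features the renderer can actuate (see Details).
#' @param cell_shape List: `radius` (um), `elongation` (base relative
#'   amplitude), `irregularity` (Fourier roughness), `n_vertices`.
#' @param base_speed Mean cell speed, um/min.
#' @param latent_ar Autoregressive persistence of each latent driver.
#' @param truncate_prob Probability a track is truncated at entry/exit,
#'   emulating cells entering or leaving the field.
#' @details Actuatable features: Instantaneous Cell Speed, Cell Compactness,
#'   Cell Area, Number of CMACs per Cell, and the per-cell Mean of CMAC
#'   Area, CMAC Lifetime, CMAC Mean EGFP-Paxillin Intensity, plus the
#'   per-cell Median paxillin-LifeAct colocalization. Edges naming any other
#'   feature are rejected.
#' @return Object of class `microscopy_sim_spec`.
#' @export
microscopy_sim_spec <- function(n_cells = 20, n_frames = 60,
                                frame_interval = 5, pixel_size = 0.21,
                                cmac_birth_rate = 2, cmac_lifetime = 8,
                                n_cmacs = 15,
                                coupling_edges = list(),
                                cell_shape = list(radius = 12,
                                                  elongation = 0.3,
                                                  irregularity = 0.12,
                                                  n_vertices = 28),
                                base_speed = 0.3, latent_ar = 0.45,
                                truncate_prob = 0) {
  stopifnot(n_frames >= 3, frame_interval > 0, pixel_size > 0,
            cmac_lifetime >= 1, n_cmacs >= 1,
            latent_ar >= 0, latent_ar < 1,
            truncate_prob >= 0, truncate_prob < 1)
  catalog <- cell_feature_catalog()$name
  for (e in coupling_edges) {
    stopifnot(all(c("source", "target", "lag", "coefficient") %in% names(e)))
    for (f in c(e$source, e$target)) {
      if (!f %in% catalog)
        stop(sprintf("coupling edge names unknown feature: '%s'", f))
      if (!f %in% .SIM_DRIVERS)
        stop(sprintf("feature '%s' is not actuatable by the renderer; use one of: %s",
                     f, paste(.SIM_DRIVERS, collapse = "; ")))
    }
    stopifnot(e$lag >= 1)
  }
  structure(list(n_cells = n_cells, n_frames = n_frames,
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 cmac_birth_rate = cmac_birth_rate,
                 cmac_lifetime = cmac_lifetime, n_cmacs = n_cmacs,
                 coupling_edges = coupling_edges, cell_shape = cell_shape,
                 base_speed = base_speed, latent_ar = latent_ar,
                 truncate_prob = truncate_prob),
            class = "microscopy_sim_spec")
}

# Latent driver VAR built from the coupling edges; checked for stationarity.
.latent_spec <- function(spec) {
  feats <- unique(unlist(lapply(spec$coupling_edges,
                                function(e) c(e$source, e$target))))
  if (!length(feats)) feats <- character(0)
  k <- length(feats)
  max_lag <- max(c(1L, vapply(spec$coupling_edges, function(e) as.integer(e$lag),
                              integer(1))))
  if (k == 0) return(NULL)
  coupling <- array(0, c(max_lag, k, k))
  for (j in seq_len(k)) coupling[1, j, j] <- spec$latent_ar
  for (e in spec$coupling_edges) {
    s <- match(e$source, feats); t <- match(e$target, feats)
    coupling[e$lag, t, s] <- coupling[e$lag, t, s] + e$coefficient
  }
  vs <- var_spec(k, max_lag, coupling,
                 noise_sd = rep(sqrt(1 - spec$latent_ar^2), k),
                 feature_names = feats)
  sr <- var_spectral_radius(vs)
  if (sr >= 1)
    stop(sprintf("injected couplings give a non-stationary latent process (spectral radius %.3f)", sr))
  vs
}

.fmt_pixels <- function(v) paste(sprintf("%.4f", v), collapse = ";")

#' Simulate a tracked-cell/CMAC dataset with known causal structure
#'
#' Renders each cell as a moving star-convex polygon with a turnover
#' population of CMACs. Latent per-cell drivers follow a stationary VAR
#' carrying the injected couplings and modulate the rendered objects
#' (speed, shape elongation, CMAC count/area/lifetime, channel intensities,
#' pixel-level colocalization); all other variation is stochastic.
#'
#' @param spec A [microscopy_sim_spec()].
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @param condition,repeat_id Labels attached to every row.
#' @return List with `dataset` (class `tracked_dataset`: data frames
#'   `cells` and `cmacs`, plus `frame_interval` and `pixel_size`) and
#'   `truth` (a [ground_truth()] of exactly the injected couplings).
#' @export
simulate_microscopy_panel <- function(spec, seed = 1, condition = "control",
                                      repeat_id = 1L) {
  stopifnot(inherits(spec, "microscopy_sim_spec"))
  set.seed(seed)
  lat <- .latent_spec(spec)
  lat_names <- if (is.null(lat)) character(0) else lat$feature_names
  pixel_area <- spec$pixel_size^2
  sh <- spec$cell_shape
  i1_0 <- 40; i2_0 <- 30; bg1_0 <- 50; bg2_0 <- 45; pix_sd <- 6
  rho0 <- 0.4
  cells_rows <- vector("list", spec$n_cells)
  cmac_rows <- vector("list", spec$n_cells)

  zval <- function(z_t, feat) if (feat %in% lat_names) z_t[match(feat, lat_names)] else 0

  for (cell in seq_len(spec$n_cells)) {
    Tn <- spec$n_frames
    # latent driver realization (burn-in inside simulate_var_panel-style loop)
    if (!is.null(lat)) {
      zsim <- simulate_var_panel(lat, 1, Tn,
                                 seed = (abs(seed) %% 2000000L) * 1000L + cell)
      z <- as.matrix(zsim$panel[, lat_names, drop = FALSE])
    } else z <- matrix(0, Tn, 0)
    # per-cell static shape roughness
    f_amp <- stats::runif(3, 0, sh$irregularity) / (1:3)
    f_phase <- stats::runif(3, 0, 2 * pi)
    phi <- stats::runif(1, 0, pi)
    theta <- stats::runif(1, 0, 2 * pi)
    pos <- stats::runif(2, 100, 400)
    # CMAC state
    st <- data.frame(id = integer(0), relx = numeric(0), rely = numeric(0),
                     birth = integer(0), death = integer(0),
                     base_area = numeric(0), q = numeric(0))
    next_id <- 1L
    crows <- vector("list", Tn)
    mrows <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      z_t <- if (ncol(z)) z[t, ] else numeric(0)
      # Smooth log-linear / logistic links from latent drivers to renderer
      # dials: positive dials use exp(), bounded dials a squashing link, so
      # rendered feature distributions stay continuous (no clip masses) and
      # a monotone power transform can re-linearize them.
      speed <- spec$base_speed * exp(0.25 * zval(z_t, "Instantaneous Cell Speed"))
      e_base <- qlogis((sh$elongation - 0.02) / 0.78)
      elong <- 0.02 + 0.78 * stats::plogis(e_base + 0.6 * zval(z_t, "Cell Compactness"))
      area_scale <- exp(0.18 * zval(z_t, "Cell Area"))
      m_target <- spec$n_cmacs * exp(0.25 * zval(z_t, "Number of CMACs per Cell"))
      casc <- exp(0.25 * zval(z_t, "Mean [CMAC Area] per Cell"))
      life_mean <- spec$cmac_lifetime *
        exp(0.35 * zval(z_t, "Mean [CMAC Lifetime] per Cell"))
      i1_t <- i1_0 * exp(0.22 * zval(z_t, "Mean [CMAC Mean EGFP-Paxillin Intensity] per Cell"))
      rho_t <- 0.95 * tanh(atanh(rho0 / 0.95) + 0.3 *
        zval(z_t, "Median [EGFP-Paxillin - RubyRed-LifeAct Colocalization per CMAC] per Cell"))
      # move cell
      theta <- theta + stats::rnorm(1, 0, 0.4)
      step <- speed * spec$frame_interval
      pos <- pos + step * c(cos(theta), sin(theta))
      phi <- phi + stats::rnorm(1, 0, 0.05)
      r_base <- sqrt(sh$radius^2 * area_scale)
      poly <- .star_polygon(pos + stats::rnorm(2, 0, 0.05), r_base, elong, phi,
                            f_amp, f_phase, sh$n_vertices)
      ctr <- polygon_properties(poly)$centroid
      crows[[t]] <- data.frame(condition = condition, repeat_id = repeat_id,
                               cell_id = cell, frame = t - 1L,
                               centroid_x_um = ctr[1], centroid_y_um = ctr[2],
                               polygon_wkt = polygon_to_wkt(poly),
                               stringsAsFactors = FALSE)
      # CMAC deaths then births toward the latent target count
      st <- st[st$death >= t, , drop = FALSE]
      n_birth <- stats::rpois(1, max(0.05, spec$cmac_birth_rate *
                                       max(0, m_target - nrow(st))))
      if (n_birth > 0) {
        ang <- stats::runif(n_birth, 0, 2 * pi)
        u <- sqrt(stats::runif(n_birth)) * 0.9
        rmax <- r_base * (1 + elong * cos(2 * (ang - phi)))
        life <- 1L + stats::rgeom(n_birth, 1 / max(1.01, life_mean))
        st <- rbind(st, data.frame(
          id = next_id:(next_id + n_birth - 1L),
          relx = u * rmax * cos(ang), rely = u * rmax * sin(ang),
          birth = t, death = t + life - 1L,
          base_area = pmax(0.12, stats::rlnorm(n_birth, log(0.45), 0.55)),
          q = stats::runif(n_birth, 1.2, 2.5)))
        next_id <- next_id + n_birth
      }
      n_al <- nrow(st)
      if (n_al > 0) {
        st$relx <- st$relx + stats::rnorm(n_al, 0, 0.08)
        st$rely <- st$rely + stats::rnorm(n_al, 0, 0.08)
        area <- pmax(0.12, st$base_area * casc * exp(stats::rnorm(n_al, 0, 0.05)))
        minor <- sqrt(4 * area / (pi * st$q))
        major <- st$q * minor
        npix <- pmax(8L, as.integer(round(area / pixel_area)))
        ch1 <- character(n_al); ch2 <- character(n_al)
        for (i in seq_len(n_al)) {
          ck <- stats::rnorm(npix[i])
          e1 <- stats::rnorm(npix[i]); e2 <- stats::rnorm(npix[i])
          sr <- sqrt(abs(rho_t)); s2 <- sign(rho_t)
          p1 <- i1_t + pix_sd * (sr * ck + sqrt(1 - abs(rho_t)) * e1)
          p2 <- i2_0 + pix_sd * (s2 * sr * ck + sqrt(1 - abs(rho_t)) * e2)
          ch1[i] <- .fmt_pixels(p1 + bg1_0)
          ch2[i] <- .fmt_pixels(p2 + bg2_0)
        }
        mrows[[t]] <- data.frame(
          condition = condition, repeat_id = repeat_id, cell_id = cell,
          cmac_id = st$id, frame = t - 1L,
          centroid_x_um = ctr[1] + st$relx, centroid_y_um = ctr[2] + st$rely,
          area_um2 = area, major_axis_um = major, minor_axis_um = minor,
          ch1_pixels = ch1, ch2_pixels = ch2,
          ch1_bg = bg1_0 + stats::rnorm(n_al, 0, 1.5),
          ch2_bg = bg2_0 + stats::rnorm(n_al, 0, 1.5),
          stringsAsFactors = FALSE)
      }
    }
    cells_rows[[cell]] <- do.call(rbind, crows)
    cmac_rows[[cell]] <- do.call(rbind, mrows[!vapply(mrows, is.null, logical(1))])
  }
  ds <- structure(list(cells = do.call(rbind, cells_rows),
                       cmacs = do.call(rbind, cmac_rows),
                       frame_interval = spec$frame_interval,
                       pixel_size = spec$pixel_size),
                  class = "tracked_dataset")
  rownames(ds$cells) <- rownames(ds$cmacs) <- NULL
  if (spec$truncate_prob > 0)
    ds <- inject_missingness(ds, spec$truncate_prob, seed = seed + 7919L)
  edges <- if (length(spec$coupling_edges)) do.call(rbind, lapply(
    spec$coupling_edges, function(e)
      data.frame(source = e$source, target = e$target,
                 sign = ifelse(e$coefficient > 0, "+", "-"),
                 lag = as.integer(e$lag), coefficient = e$coefficient,
                 stringsAsFactors = FALSE)))
  else data.frame(source = character(0), target = character(0),
                  sign = character(0), lag = integer(0),
                  coefficient = numeric(0), stringsAsFactors = FALSE)
  list(dataset = ds, truth = ground_truth(edges, params = list(spec = spec)))
}

#' @export
print.tracked_dataset <- function(x, ...) {
  cat(sprintf(paste0("Tracked dataset: %d cell-frame rows (%d cells), ",
                     "%d CMAC-frame rows; frame interval %g min, pixel %g um\n"),
              nrow(x$cells),
              nrow(unique(x$cells[, c("condition", "repeat_id", "cell_id")])),
              nrow(x$cmacs), x$frame_interval, x$pixel_size))
  invisible(x)
}

#' Truncate tracks at random entry/exit frames
#'
#' Emulates cells entering and exiting the imaging field: each track is,
#' independently with probability `rate`, truncated at its start and/or end.
#' Tracks stay contiguous (no interior gaps) and never drop below 2 frames.
#'
#' @param dataset A `tracked_dataset`.
#' @param rate Entry/exit probability in `[0, 1)`.
#' @param seed Integer seed (deterministic truncation pattern).
#' @return The truncated `tracked_dataset`.
#' @export
inject_missingness <- function(dataset, rate, seed = 1) {
  stopifnot(inherits(dataset, "tracked_dataset"))
  if (!(is.numeric(rate) && length(rate) == 1 && rate >= 0 && rate < 1))
    stop("rate must be a probability in [0, 1)")
  if (rate == 0) return(dataset)
  set.seed(seed)
  key <- interaction(dataset$cells$condition, dataset$cells$repeat_id,
                     dataset$cells$cell_id, drop = TRUE)
  keep <- rep(TRUE, nrow(dataset$cells))
  windows <- list()
  for (k in levels(key)) {
    idx <- which(key == k)
    fr <- dataset$cells$frame[idx]
    lo <- min(fr); hi <- max(fr)
    if (stats::runif(1) < rate && hi - lo >= 2)
      lo <- lo + sample.int(hi - lo - 1, 1)   # keep >= 2 frames
    if (stats::runif(1) < rate && hi - lo >= 2)
      hi <- hi - sample.int(hi - lo - 1, 1)
    keep[idx[fr < lo | fr > hi]] <- FALSE
    windows[[k]] <- c(lo, hi)
  }
  dataset$cells <- dataset$cells[keep, , drop = FALSE]
  mkey <- paste(dataset$cmacs$condition, dataset$cmacs$repeat_id,
                dataset$cmacs$cell_id, sep = ".")
  wlo <- vapply(windows, `[`, numeric(1), 1)[mkey]
  whi <- vapply(windows, `[`, numeric(1), 2)[mkey]
  ok <- !is.na(wlo) & dataset$cmacs$frame >= wlo & dataset$cmacs$frame <= whi
  dataset$cmacs <- dataset$cmacs[ok, , drop = FALSE]
  rownames(dataset$cells) <- rownames(dataset$cmacs) <- NULL
  dataset
}
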