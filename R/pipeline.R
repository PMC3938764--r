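# Orchestration, configuration and file interchange. Coordinates are um,
# frames are 0-based, the frame interval is stored once per dataset; CSV
# with explicit headers (WKT polygons) is the interchange format.

# Small stable string hash (FNV-1a, 32-bit), used for config fingerprints
# and stage-seed derivation; avoids any binary dependency.
.hash32 <- function(s) {
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) {
    h <- bitwXor(as.integer(h %% 2147483647), x)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

#' Derive a stage seed from the master seed
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name.
#' @return Integer below 2^31, stable in the stage name and master seed.
#' @export
stage_seed <- function(master_seed, stage)
  (.hash32(paste0(stage, ":", master_seed)) %% 2000000000L) + 1L

.CONFIG_DEFAULTS <- function() list(
  input_dir = NULL,              # read cells.csv/cmacs.csv from here, or
  simulate = NULL,               # named list of microscopy_sim_spec per condition
  reference_condition = "control",
  frame_interval = 5,
  seed = 1L,
  smooth_trajectories = TRUE,
  boxcox_alpha = 0.01,
  keep_features = character(0),
  stationarity_min_fraction = 0.8,
  analysis_features = NULL,      # features carried into transforms/granger
  granger_features = NULL,       # features wired into the causal graph
  lag_max = 10L,
  en_alpha = 0.5,
  em_restarts = 10L,
  em_final_restarts = 100L,
  k_range = 2:8,
  variance_target = 0.85,
  edge_frac_sig = 0.6,
  edge_frac_strong = 0.25,
  edge_alpha = 0.05,
  edge_strong_alpha = 1e-4,
  sign_method = "spearman",
  run_population_structure = FALSE,
  run_selection = FALSE,
  run_granger = TRUE)

#' Build a validated pipeline run configuration
#'
#' Every parameter has a default; unknown keys are rejected before
#' execution. The configuration round-trips losslessly through YAML
#' except for in-memory simulation specs.
#'
#' @param ... Overrides of the defaults (see the source for the full set:
#'   inputs, reference condition, stage toggles, lag maximum, elastic-net
#'   alpha, EM restarts, edge-criterion thresholds, master seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .CONFIG_DEFAULTS()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(ov)] <- ov
  if (is.null(cfg$input_dir) && is.null(cfg$simulate))
    stop("config needs either input_dir or simulate")
  structure(cfg, class = "run_config")
}

.config_hash <- function(cfg) {
  flat <- paste(utils::capture.output(utils::str(unclass(cfg),
                                                 give.attr = FALSE)),
                collapse = "\n")
  sprintf("%08x", .hash32(flat))
}

.write_table <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

.read_table <- function(path)
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)

#' Write a tracked dataset as delimited tables
#'
#' Emits `cells.csv` and `cmacs.csv` (schema: um coordinates, 0-based
#' frames, WKT polygons, semicolon-joined pixel vectors) plus
#' `meta.json` with the frame interval and pixel size.
#'
#' @param dataset A `tracked_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tracked_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tracked_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$cmacs, file.path(dir, "cmacs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(frame_interval = dataset$frame_interval,
                            pixel_size = dataset$pixel_size),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a tracked dataset from delimited tables
#'
#' Validates the schema, per-track frame contiguity and positivity of
#' areas; rejects with row references on violation.
#'
#' @param dir Directory holding `cells.csv`, `cmacs.csv` and
#'   (optionally) `meta.json`.
#' @return A `tracked_dataset`.
#' @export
read_tracked_tables <- function(dir) {
  cells <- .read_table(file.path(dir, "cells.csv"))
  cmacs <- .read_table(file.path(dir, "cmacs.csv"))
  need_cells <- c("condition", "repeat_id", "cell_id", "frame",
                  "centroid_x_um", "centroid_y_um", "polygon_wkt")
  need_cmacs <- c("condition", "repeat_id", "cell_id", "cmac_id", "frame",
                  "centroid_x_um", "centroid_y_um", "area_um2",
                  "major_axis_um", "minor_axis_um", "ch1_pixels",
                  "ch2_pixels", "ch1_bg", "ch2_bg")
  miss <- setdiff(need_cells, names(cells))
  if (length(miss)) stop("cells.csv missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_cmacs, names(cmacs))
  if (length(miss)) stop("cmacs.csv missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- .track_key(cells)
  for (k in unique(key)) {
    fr <- sort(cells$frame[key == k])
    if (length(fr) > 1 && any(diff(fr) != 1))
      stop(sprintf("non-contiguous frames in cell track %s",
                   gsub("\r", "/", k)))
  }
  if (any(cmacs$area_um2 <= 0))
    stop(sprintf("non-positive CMAC area at row(s) %s",
                 paste(utils::head(which(cmacs$area_um2 <= 0), 5),
                       collapse = ", ")))
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(frame_interval = 5, pixel_size = 0.21)
  structure(list(cells = cells, cmacs = cmacs,
                 frame_interval = meta$frame_interval,
                 pixel_size = meta$pixel_size),
            class = "tracked_dataset")
}

#' Write a ground-truth graph as JSON
#' @param truth A [ground_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth$edges, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# dataset -> cell feature panel, one condition set at a time
.extract_features <- function(dataset, cfg) {
  cm <- correct_local_background(dataset$cmacs)
  pr <- parse_cmac_tracks(cm)
  std <- standardize_intensities(pr$cmacs,
                                 reference_condition = cfg$reference_condition)
  cmf <- compute_cmac_features(std$cmacs, dataset$cells,
                               frame_interval = dataset$frame_interval)
  panel <- compute_cell_features(dataset$cells, cmf,
                                 frame_interval = dataset$frame_interval,
                                 smooth = cfg$smooth_trajectories)
  list(panel = panel, cmac_features = cmf, parsing_report = pr$report,
       divisors = std$divisors)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- feature extraction, Box-Cox
#' normalization and stationarity verification, optional subpopulation
#' structure and feature selection, Granger causal-graph inference per
#' condition and, with two or more conditions, the cross-condition
#' plasticity comparison -- and writes every stage output plus a
#' provenance manifest to `out_dir`. Fully deterministic under a fixed
#' master seed (stage seeds are derived by stable hashing).
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @return List of in-memory stage results (`panel`, `normalized`,
#'   `stationarity`, `graphs`, `plasticity`, ...), invisibly writes files.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cellwiring_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  manifest <- list(package_version = as.character(utils::packageVersion("cellwiring")),
                   config_hash = hash, seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # --- input ---------------------------------------------------------
  truths <- list()
  if (!is.null(config$input_dir)) {
    dataset <- read_tracked_tables(config$input_dir)
  } else {
    sims <- lapply(names(config$simulate), function(cond)
      simulate_microscopy_panel(config$simulate[[cond]],
                                seed = stage_seed(config$seed,
                                                  paste0("simulate:", cond)),
                                condition = cond))
    names(sims) <- names(config$simulate)
    truths <- lapply(sims, `[[`, "truth")
    dataset <- structure(list(
      cells = do.call(rbind, lapply(sims, function(s) s$dataset$cells)),
      cmacs = do.call(rbind, lapply(sims, function(s) s$dataset$cmacs)),
      frame_interval = sims[[1]]$dataset$frame_interval,
      pixel_size = sims[[1]]$dataset$pixel_size), class = "tracked_dataset")
    rownames(dataset$cells) <- rownames(dataset$cmacs) <- NULL
  }
  note("input", n_cell_rows = nrow(dataset$cells),
       n_cmac_rows = nrow(dataset$cmacs))

  # --- features ------------------------------------------------------
  fx <- .extract_features(dataset, config)
  panel <- fx$panel
  .write_table(panel, file.path(out_dir, "features_cell.csv"), hash)
  .write_table(fx$cmac_features, file.path(out_dir, "features_cmac.csv"),
               hash)
  note("features", n_rows = nrow(panel),
       parsing = fx$parsing_report)

  # --- transforms ----------------------------------------------------
  feats <- config$analysis_features
  if (is.null(feats))
    feats <- intersect(cell_feature_catalog()$name, names(panel))
  nm <- normalize_panel(panel, features = feats, alpha = config$boxcox_alpha,
                        keep = config$keep_features)
  .write_table(nm$panel, file.path(out_dir, "features_cell_normalized.csv"),
               hash)
  tr <- lapply(nm$transforms, function(t)
    list(lambda = t$lambda, shift = t$shift, verdict = t$verdict))
  jsonlite::write_json(tr, file.path(out_dir, "transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  kept <- setdiff(feats, nm$discarded)
  st <- suppressWarnings(
    check_stationarity(nm$panel,
                       features = intersect(kept,
                                            if (is.null(config$granger_features))
                                              kept else config$granger_features),
                       min_fraction = config$stationarity_min_fraction))
  .write_table(st, file.path(out_dir, "stationarity.csv"), hash)
  note("transforms", discarded = nm$discarded,
       n_organizational_kept = sum(kept != "Instantaneous Cell Speed"))

  res <- list(panel = panel, normalized = nm, stationarity = st,
              truths = truths, parsing_report = fx$parsing_report,
              manifest = manifest)

  # --- population structure -----------------------------------------
  if (isTRUE(config$run_population_structure)) {
    org <- intersect(organizational_features(), names(nm$panel))
    x <- as.matrix(nm$panel[stats::complete.cases(nm$panel[, org]), org])
    pc <- pca_svd(x)
    nc <- n_components_for_variance(pc$variance_fraction,
                                    config$variance_target)
    sel <- select_n_subpopulations(pc$scores[, seq_len(nc), drop = FALSE],
                                   k_range = config$k_range,
                                   restarts = config$em_restarts,
                                   final_restarts = config$em_final_restarts,
                                   seed = stage_seed(config$seed, "subpop"))
    .write_table(sel$aic_curve, file.path(out_dir, "aic_curve.csv"), hash)
    .write_table(data.frame(label = sel$fit$labels),
                 file.path(out_dir, "subpopulations.csv"), hash)
    res$subpopulations <- sel
    note("population_structure", best_k = sel$best_k, n_components = nc)
  }

  # --- feature selection --------------------------------------------
  if (isTRUE(config$run_selection)) {
    org <- intersect(organizational_features(), names(nm$panel))
    cv <- cva_rank_features(nm$panel, features = org)
    en <- elastic_net_rank(nm$panel, features = org, alpha = config$en_alpha)
    sp <- spearman_matrix(nm$panel)
    .write_table(cv$ranking, file.path(out_dir, "cva_ranking.csv"), hash)
    .write_table(en$ranking, file.path(out_dir, "en_ranking.csv"), hash)
    .write_table(en$path, file.path(out_dir, "en_path.csv"), hash)
    .write_table(as.data.frame(sp), file.path(out_dir, "spearman_matrix.csv"),
                 hash)
    res$selection <- list(cva = cv, en = en, spearman = sp)
    note("selection", en_opt_iteration = en$opt_iteration)
  }

  # --- granger + comparison -----------------------------------------
  if (isTRUE(config$run_granger)) {
    gf <- config$granger_features
    if (is.null(gf))
      stop("run_granger requires granger_features in the config")
    gf <- intersect(gf, names(nm$panel))
    crit <- edge_criterion(config$edge_frac_sig, config$edge_frac_strong,
                           config$edge_alpha, config$edge_strong_alpha)
    conds <- unique(nm$panel$condition)
    graphs <- lapply(conds, function(cond)
      causal_graph(nm$panel[nm$panel$condition == cond, , drop = FALSE],
                   features = gf, condition = cond,
                   L_max = config$lag_max, criterion = crit,
                   sign_method = config$sign_method))
    names(graphs) <- conds
    for (cond in conds) {
      g <- graphs[[cond]]
      jsonlite::write_json(g$edges,
                           file.path(out_dir,
                                     sprintf("graph_%s.json", cond)),
                           auto_unbox = TRUE, digits = NA)
      for (nm2 in names(g$tests)) {
        t2 <- g$tests[[nm2]]
        for (gr in list(t2$grid_xy, t2$grid_yx)) {
          fn <- sprintf("siggrid_%s__%s__%s.csv", cond,
                        gsub("[^A-Za-z0-9]+", "_", gr$x),
                        gsub("[^A-Za-z0-9]+", "_", gr$y))
          .write_table(data.frame(p_x = rep(seq_len(gr$L_max), gr$L_max),
                                  p_y = rep(seq_len(gr$L_max),
                                            each = gr$L_max),
                                  p = as.vector(gr$p),
                                  bin = as.vector(gr$bin),
                                  sign = as.vector(gr$sign),
                                  adj_r2 = as.vector(gr$adj_r2)),
                       file.path(out_dir, fn), hash)
        }
      }
    }
    res$graphs <- graphs
    note("granger", n_conditions = length(conds),
         edges = vapply(graphs, function(g) nrow(g$edges), integer(1)))
    if (length(graphs) >= 2) {
      pl <- compare_conditions(graphs)
      .write_table(pl$table, file.path(out_dir, "plasticity_report.csv"),
                   hash)
      res$plasticity <- pl
      note("comparison", counts = as.list(pl$counts))
    }
  }

  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  res$out_dir <- out_dir
  res
}
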