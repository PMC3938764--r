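# Stationary VAR panel generator: one independent realization per simulated
# cell, used as the ground-truth benchmark for the Granger stage.

#' Specify a vector-autoregressive generating process
#'
#' @param n_features Number of features (VAR dimension).
#' @param lag_order Number of lags (>= 1).
#' @param coupling 3-D coefficient array, dim `c(lag_order, n_features,
#'   n_features)`, entry `[l, j, i]` the effect of feature `i` at lag `l`
#'   on feature `j`. Defaults to diagonal AR(1) with coefficient 0.5.
#' @param noise_sd Per-feature innovation standard deviations (> 0).
#' @param feature_means Per-feature process means.
#' @param feature_names Optional feature names (default `F1..Fk`).
#' @return Object of class `var_spec`.
#' @export
var_spec <- function(n_features, lag_order = 1, coupling = NULL,
                     noise_sd = rep(1, n_features),
                     feature_means = rep(0, n_features),
                     feature_names = NULL) {
  stopifnot(n_features >= 1, lag_order >= 1)
  if (is.null(coupling)) {
    coupling <- array(0, c(lag_order, n_features, n_features))
    for (j in seq_len(n_features)) coupling[1, j, j] <- 0.5
  }
  stopifnot(length(dim(coupling)) == 3,
            all(dim(coupling) == c(lag_order, n_features, n_features)))
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  stopifnot(length(noise_sd) == n_features,
            length(feature_means) == n_features)
  if (is.null(feature_names)) feature_names <- paste0("F", seq_len(n_features))
  structure(list(n_features = n_features, lag_order = lag_order,
                 coupling = coupling, noise_sd = noise_sd,
                 feature_means = feature_means,
                 feature_names = feature_names),
            class = "var_spec")
}

#' Spectral radius of the VAR companion matrix
#'
#' The process is stationary iff this is < 1.
#'
#' @param spec A [var_spec()].
#' @return The companion-matrix spectral radius.
#' @export
var_spectral_radius <- function(spec) {
  k <- spec$n_features; p <- spec$lag_order
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p))
    comp[seq_len(k), (l - 1) * k + seq_len(k)] <- spec$coupling[l, , ]
  if (p > 1)
    comp[k + seq_len(k * (p - 1)), seq_len(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Ground-truth causal graph of a generator
#'
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (`"+"`/`"-"`), `lag`, `coefficient`.
#' @param params Generator parameter echo (list).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(edges, params = list()) {
  stopifnot(all(c("source", "target", "sign", "lag", "coefficient") %in%
                  names(edges)))
  stopifnot(all(edges$sign %in% c("+", "-")))
  structure(list(edges = edges, params = params), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth causal graph:", nrow(x$edges), "edge(s)\n")
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s (%s, lag %d, coef %.3g)\n",
                  x$edges$source[i], x$edges$target[i], x$edges$sign[i],
                  x$edges$lag[i], x$edges$coefficient[i]))
  invisible(x)
}

.ground_truth_from_coupling <- function(spec, include_self = FALSE) {
  idx <- which(spec$coupling != 0, arr.ind = TRUE)
  keep <- include_self | (idx[, 2] != idx[, 3])
  idx <- idx[keep, , drop = FALSE]
  co <- spec$coupling[cbind(idx[, 1], idx[, 2], idx[, 3])]
  ground_truth(data.frame(
    source = spec$feature_names[idx[, 3]],
    target = spec$feature_names[idx[, 2]],
    sign = ifelse(co > 0, "+", "-"),
    lag = idx[, 1], coefficient = co, stringsAsFactors = FALSE),
    params = list(spec = spec))
}

#' Simulate a multi-cell VAR feature panel
#'
#' Draws one independent stationary VAR realization per simulated cell and
#' stacks them into a long feature panel (the structure behind pooled
#' auto-regression over thousands of per-cell observations). A burn-in of
#' 100 frames is discarded so each track starts at stationarity.
#'
#' @param spec A [var_spec()]; must be stationary.
#' @param n_cells Number of cell tracks.
#' @param track_length Either a single track length (frames) or a function
#'   `function(n)` returning `n` integer lengths (each >= lag_order + 1).
#' @param seed Integer seed; the run is bit-reproducible.
#' @param condition,repeat_id Labels attached to every row.
#' @return List with `panel` (data frame: condition, repeat_id, cell_id,
#'   frame, one column per feature) and `truth` (a [ground_truth()] listing
#'   exactly the nonzero cross-feature couplings).
#' @export
#' @examples
#' sp <- var_spec(2)
#' sp$coupling[1, 2, 1] <- -0.4   # F1 -> F2, negative, lag 1
#' sim <- simulate_var_panel(sp, n_cells = 5, track_length = 30, seed = 1)
#' head(sim$panel); sim$truth
simulate_var_panel <- function(spec, n_cells, track_length = 50, seed = 1,
                               condition = "control", repeat_id = 1L) {
  stopifnot(inherits(spec, "var_spec"))
  sr <- var_spectral_radius(spec)
  if (sr >= 1)
    stop(sprintf("non-stationary VAR spec: companion spectral radius %.4f >= 1", sr))
  lengths <- if (is.function(track_length)) track_length(n_cells)
             else rep(as.integer(track_length), n_cells)
  if (any(lengths < spec$lag_order + 1))
    stop("track lengths must be >= lag_order + 1")
  k <- spec$n_features; p <- spec$lag_order
  burn <- 100L
  set.seed(seed)
  rows <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    t_total <- lengths[cell] + burn
    z <- matrix(0, t_total, k)
    eps <- matrix(stats::rnorm(t_total * k), t_total, k)
    eps <- sweep(eps, 2, spec$noise_sd, `*`)
    for (t in seq_len(t_total)) {
      acc <- eps[t, ]
      for (l in seq_len(min(p, t - 1)))
        acc <- acc + spec$coupling[l, , ] %*% z[t - l, ]
      z[t, ] <- acc
    }
    z <- z[(burn + 1):t_total, , drop = FALSE]
    z <- sweep(z, 2, spec$feature_means, `+`)
    colnames(z) <- spec$feature_names
    rows[[cell]] <- data.frame(condition = condition, repeat_id = repeat_id,
                               cell_id = cell,
                               frame = seq_len(lengths[cell]) - 1L,
                               z, check.names = FALSE,
                               stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  list(panel = panel, truth = .ground_truth_from_coupling(spec))
}
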