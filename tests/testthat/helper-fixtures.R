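# Shared fixture builders. Everything is generated in code at test time.

# Bivariate VAR(1) spec with one directed cross-coupling F1 -> F2.
coupled_var_spec <- function(coef = -0.5, ar = 0.5) {
  sp <- var_spec(2, coupling = array(c(ar, 0, 0, ar), c(1, 2, 2)))
  sp$coupling[1, 2, 1] <- coef
  sp
}

# Independent AR(1) pair (null panel for type-I checks).
null_var_spec <- function(ar = 0.5)
  var_spec(2, coupling = array(c(ar, 0, 0, ar), c(1, 2, 2)))

# Well-separated K-component Gaussian score matrix.
gaussian_clusters <- function(seed, k = 4, d = 4, delta = 8, n_per = 500) {
  set.seed(seed)
  mu <- matrix(0, k, d)
  for (i in seq_len(k - 1)) mu[i + 1, ((i - 1) %% d) + 1] <- delta * i / i
  if (k >= 2) mu[2, 1] <- delta
  if (k >= 3) mu[3, min(2, d)] <- delta
  if (k >= 4) mu[4, min(3, d)] <- delta
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_per * d), n_per, d), 2, mu[i, ], `+`)))
  list(x = x, labels = rep(seq_len(k), each = n_per), means = mu)
}

# Small simulated tracked dataset reused across feature tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- microscopy_sim_spec(n_cells = 4, n_frames = 15)
      cache <<- simulate_microscopy_panel(spec, seed = 42)
    }
    cache
  }
})

# Feature panel wrapper around plain columns, for the statistics modules.
as_panel <- function(..., condition = "control") {
  d <- data.frame(..., check.names = FALSE)
  n <- nrow(d)
  cbind(data.frame(condition = condition, repeat_id = 1L,
                   cell_id = seq_len(n), frame = 0L), d)
}

# A panel of independent per-cell AR(1) tracks for one named feature set.
ar1_panel <- function(features, n_cells, track_length, seed, ar = 0.5) {
  k <- length(features)
  cp <- array(0, c(1, k, k))
  for (j in seq_len(k)) cp[1, j, j] <- ar
  sp <- var_spec(k, coupling = cp, feature_names = features)
  simulate_var_panel(sp, n_cells, track_length, seed = seed)$panel
}
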