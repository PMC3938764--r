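# Pooled auto-regressive Granger causality over the cell panel: lagged
# design construction (lags never cross track, condition or repeat
# boundaries), OLS fitting, adjusted-R2 lag surfaces, and the
# Granger-Sargent nested-model test.

# Within-track lag embedding for a (Y, X) pair over the whole panel.
# Tracks are the (condition, repeat_id, cell_id) series ordered by frame;
# lag l of a value is the value l frames earlier in the same track.
.lag_matrix <- function(panel, y, x = NULL, L = 10) {
  stopifnot(y %in% names(panel), is.null(x) || x %in% names(panel))
  key <- .track_key(panel)
  ord <- order(key, panel$frame)
  panel <- panel[ord, , drop = FALSE]
  key <- key[ord]
  pos <- stats::ave(seq_along(key), key, FUN = seq_along)
  shift <- function(v, l) c(rep(NA_real_, l), v[seq_len(length(v) - l)])
  n <- nrow(panel)
  yv <- panel[[y]]
  ylags <- sapply(seq_len(L), function(l) {
    s <- shift(yv, l); s[pos <= l] <- NA; s
  })
  xlags <- if (!is.null(x)) {
    xv <- panel[[x]]
    sapply(seq_len(L), function(l) {
      s <- shift(xv, l); s[pos <= l] <- NA; s
    })
  } else NULL
  list(y = yv, x = if (!is.null(x)) panel[[x]] else NULL,
       ylags = matrix(ylags, n, L), xlags = if (!is.null(x))
         matrix(xlags, n, L) else NULL,
       pos = pos, track = key, L = L)
}

.design_at <- function(lm_obj, p_y, p_x) {
  m <- max(p_y, p_x)
  rows <- lm_obj$pos > m & !is.na(lm_obj$y)
  if (p_y > 0)
    rows <- rows & rowSums(is.na(lm_obj$ylags[, seq_len(p_y),
                                              drop = FALSE])) == 0
  if (p_x > 0)
    rows <- rows & rowSums(is.na(lm_obj$xlags[, seq_len(p_x),
                                              drop = FALSE])) == 0
  X <- cbind(intercept = 1,
             if (p_y > 0) lm_obj$ylags[rows, seq_len(p_y), drop = FALSE],
             if (p_x > 0) lm_obj$xlags[rows, seq_len(p_x), drop = FALSE])
  cn <- c("intercept",
          if (p_y > 0) paste0("y_lag", seq_len(p_y)),
          if (p_x > 0) paste0("x_lag", seq_len(p_x)))
  colnames(X) <- cn
  list(y = lm_obj$y[rows], X = X, track = lm_obj$track[rows],
       n = sum(rows), p_y = p_y, p_x = p_x)
}

#' Build a pooled lagged regression design
#'
#' Stacks, across every cell track of the panel, the rows regressing the
#' response feature on its own lags 1..`p_y` and the background feature's
#' lags 1..`p_x` (younger lags are always retained alongside older ones).
#' A track of length T contributes `max(0, T - max(p_y, p_x))` rows; rows
#' never span two tracks, conditions or repeats.
#'
#' @param panel Feature panel.
#' @param y Response feature name.
#' @param x Background feature name (ignored when `p_x = 0`).
#' @param p_y Response lag count (>= 1).
#' @param p_x Background lag count (0 gives the restricted,
#'   response-only model).
#' @return List: `y` (response vector), `X` (design matrix with intercept),
#'   `track` (cell tag per row), `n`, `p_y`, `p_x`.
#' @export
build_lagged_design <- function(panel, y, x = NULL, p_y, p_x = 0) {
  stopifnot(p_y >= 1, p_x >= 0)
  lm_obj <- .lag_matrix(panel, y, if (p_x > 0) x else NULL,
                        L = max(p_y, p_x))
  d <- .design_at(lm_obj, p_y, p_x)
  if (d$n < ncol(d$X) + 5)
    stop(sprintf("design refused: %d rows for %d columns", d$n, ncol(d$X)))
  d
}

#' Fit a pooled auto-regression by ordinary least squares
#'
#' @param design Output of [build_lagged_design()].
#' @return List: `coefficients`, `rss`, `r2`, `adj_r2` (with p = regressor
#'   count excluding the intercept), `n`, `p`. A rank-deficient design is
#'   refused with a diagnostic.
#' @export
fit_pooled_ar <- function(design) {
  f <- stats::lm.fit(design$X, design$y)
  if (f$rank < ncol(design$X))
    stop(sprintf("rank-deficient design (rank %d < %d columns)",
                 f$rank, ncol(design$X)))
  rss <- sum(f$residuals^2)
  tss <- sum((design$y - mean(design$y))^2)
  r2 <- 1 - rss / tss
  p <- ncol(design$X) - 1
  n <- design$n
  list(coefficients = f$coefficients, rss = rss, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 1 - p), n = n, p = p)
}

#' Granger-Sargent test statistic and p-value
#'
#' Significance of the reduction in residual sum of squares when the
#' background feature's lags are added to the nested auto-regression.
#' F-form (default):
#' `((RSS_A - RSS_B)/p_x) / (RSS_B/(N - 1 - p_y - p_x))` referred to
#' `F(p_x, N - 1 - p_y - p_x)`; the asymptotic chi-square form
#' `N (RSS_A - RSS_B)/RSS_B` on `p_x` degrees of freedom is available via
#' `form = "chisq"`.
#'
#' @param rss_restricted RSS of model A (response lags only).
#' @param rss_unrestricted RSS of model B (response and background lags);
#'   must be positive and not exceed `rss_restricted` beyond rounding.
#' @param p_x,p_y Background/response lag counts of model B.
#' @param n Pooled row count (identical rows for both models).
#' @param form `"f"` or `"chisq"`.
#' @return List: `statistic`, `p_value`, `df`.
#' @export
granger_sargent <- function(rss_restricted, rss_unrestricted, p_x, p_y, n,
                            form = c("f", "chisq")) {
  form <- match.arg(form)
  stopifnot(p_x >= 1, p_y >= 1)
  if (rss_unrestricted <= 0) stop("unrestricted RSS must be positive")
  delta <- max(0, rss_restricted - rss_unrestricted)
  if (form == "f") {
    df2 <- n - 1 - p_y - p_x
    if (df2 <= 0) stop("not enough rows for the unrestricted model")
    stat <- (delta / p_x) / (rss_unrestricted / df2)
    list(statistic = stat,
         p_value = stats::pf(stat, p_x, df2, lower.tail = FALSE),
         df = c(p_x, df2))
  } else {
    stat <- n * delta / rss_unrestricted
    list(statistic = stat,
         p_value = stats::pchisq(stat, p_x, lower.tail = FALSE),
         df = p_x)
  }
}

#' Fit the nested lag-model pair for one grid cell
#'
#' Fits model B (lags of both response and background) and model A (the
#' same rows, response lags only) and packages the quantities the
#' Granger-Sargent test needs.
#'
#' @param panel Feature panel.
#' @param y,x Response and background feature names.
#' @param p_y,p_x Lag counts (`p_y >= 1`, `p_x >= 1`).
#' @return Object of class `lag_model_pair`: `rss_restricted`,
#'   `rss_unrestricted`, `adj_r2_restricted`, `adj_r2_unrestricted`,
#'   `n`, `p_y`, `p_x`, `coefficients` (model B).
#' @export
lag_model_pair <- function(panel, y, x, p_y, p_x) {
  stopifnot(p_x >= 1)
  d_b <- build_lagged_design(panel, y, x, p_y, p_x)
  f_b <- fit_pooled_ar(d_b)
  d_a <- d_b
  d_a$X <- d_b$X[, !grepl("^x_lag", colnames(d_b$X)), drop = FALSE]
  f_a <- fit_pooled_ar(d_a)
  structure(list(y = y, x = x, p_y = p_y, p_x = p_x, n = f_b$n,
                 rss_restricted = f_a$rss, rss_unrestricted = f_b$rss,
                 adj_r2_restricted = f_a$adj_r2,
                 adj_r2_unrestricted = f_b$adj_r2,
                 coefficients = f_b$coefficients),
            class = "lag_model_pair")
}

#' Granger-Sargent test of a fitted lag-model pair
#'
#' @param pair A [lag_model_pair()].
#' @param form Test form, `"f"` (default) or `"chisq"`.
#' @return List: `statistic`, `p_value`, `df`.
#' @export
granger_sargent_test <- function(pair, form = c("f", "chisq")) {
  stopifnot(inherits(pair, "lag_model_pair"))
  granger_sargent(pair$rss_restricted, pair$rss_unrestricted,
                  pair$p_x, pair$p_y, pair$n, form = form)
}

# Pooled within-track autocorrelation of a feature at lags 0..L
.track_acf <- function(lm_obj) {
  L <- lm_obj$L
  out <- numeric(L + 1)
  out[1] <- 1
  for (l in seq_len(L)) {
    ok <- !is.na(lm_obj$ylags[, l]) & !is.na(lm_obj$y)
    out[l + 1] <- if (sum(ok) > 2)
      stats::cor(lm_obj$y[ok], lm_obj$ylags[ok, l]) else NA_real_
  }
  out
}

.SIG_LEVELS <- c(0.05, 0.01, 0.001, 0.0001)
.SIG_LABELS <- c("ns", "<0.05", "<0.01", "<0.001", "<0.0001")

.bin_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001",
                ifelse(p < 1e-3, "<0.001",
                       ifelse(p < 0.01, "<0.01",
                              ifelse(p < 0.05, "<0.05", "ns")))))
}

#' Adjusted-R2 lag surface for one feature pair
#'
#' Adjusted R-squared of the pooled auto-regression of the response on its
#' own lags 1..p_y plus the background feature's lags 1..p_x, over the
#' full grid (p_x, p_y) in 1..`L_max` squared, together with the two
#' marginal curves (response-only and background-only models).
#'
#' @param panel Feature panel (normalized, stationarity-checked).
#' @param y,x Response and background feature names.
#' @param L_max Maximal lag (default 10).
#' @return Object of class `lag_surface`: `adj_r2` (L x L matrix, rows =
#'   background lags p_x, columns = response lags p_y), `y_only`,
#'   `x_only` (length-L marginal adjusted-R2 curves), `n` (row counts).
#'   Cells with too few rows are missing.
#' @export
r2_surface <- function(panel, y, x, L_max = 10) {
  lm_obj <- .lag_matrix(panel, y, x, L_max)
  adj <- nmat <- matrix(NA_real_, L_max, L_max,
                        dimnames = list(p_x = seq_len(L_max),
                                        p_y = seq_len(L_max)))
  y_only <- x_only <- rep(NA_real_, L_max)
  for (p_y in seq_len(L_max)) {
    d <- .design_at(lm_obj, p_y, 0)
    if (d$n >= ncol(d$X) + 5) y_only[p_y] <- fit_pooled_ar(d)$adj_r2
  }
  for (p_x in seq_len(L_max)) {
    d <- .design_at(lm_obj, 0, p_x)
    if (d$n >= ncol(d$X) + 5) x_only[p_x] <- fit_pooled_ar(d)$adj_r2
  }
  for (p_x in seq_len(L_max)) for (p_y in seq_len(L_max)) {
    d <- .design_at(lm_obj, p_y, p_x)
    if (d$n < ncol(d$X) + 5) next
    f <- fit_pooled_ar(d)
    adj[p_x, p_y] <- f$adj_r2
    nmat[p_x, p_y] <- f$n
  }
  structure(list(y = y, x = x, L_max = L_max, adj_r2 = adj,
                 y_only = y_only, x_only = x_only, n = nmat),
            class = "lag_surface")
}

#' @export
print.lag_surface <- function(x, ...) {
  cat(sprintf("Adjusted-R2 lag surface: %s ~ lags of itself + lags of %s (1..%d)\n",
              x$y, x$x, x$L_max))
  cat(sprintf("max adjusted R2: %.3f (response-only max %.3f)\n",
              max(x$adj_r2, na.rm = TRUE), max(x$y_only, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.lag_surface <- function(x, ...) {
  graphics::persp(seq_len(x$L_max), seq_len(x$L_max), x$adj_r2,
                  xlab = paste("lags of", x$x), ylab = paste("lags of", x$y),
                  zlab = "adjusted R2", theta = -35, phi = 25,
                  ticktype = "detailed", ...)
  invisible(x)
}

#' Signed Granger-Sargent significance grid
#'
#' Granger-Sargent p-values over the full (p_x, p_y) lag grid, binned into
#' the four significance levels (<0.05, <0.01, <0.001, <0.0001), with the
#' correlation sign between background and response attached (blue/red
#' semantics) and the response autocorrelation sequence for the stem plot.
#'
#' @param panel Feature panel.
#' @param y,x Response and background feature names.
#' @param L_max Maximal lag (default 10; the grid is `L_max` squared).
#' @param sign_method `"spearman"` (default): sign of the panel-level
#'   Spearman correlation between background and response, applied to the
#'   grid; `"coefficients"`: per-cell sign of the summed background-lag
#'   coefficients.
#' @param form Granger-Sargent test form.
#' @return Object of class `sig_grid`: matrices `p`, `bin`, `sign`,
#'   `adj_r2`, `n` (rows = p_x, cols = p_y), `autocorrelation` (lags
#'   0..L_max, 1 at lag 0), `spearman` (panel-level correlation), plus the
#'   marginal curves of [r2_surface()].
#' @export
significance_grid <- function(panel, y, x, L_max = 10,
                              sign_method = c("spearman", "coefficients"),
                              form = c("f", "chisq")) {
  sign_method <- match.arg(sign_method)
  form <- match.arg(form)
  lm_obj <- .lag_matrix(panel, y, x, L_max)
  dn <- list(p_x = seq_len(L_max), p_y = seq_len(L_max))
  pmat <- adj <- nmat <- matrix(NA_real_, L_max, L_max, dimnames = dn)
  smat <- matrix(NA_character_, L_max, L_max, dimnames = dn)
  ok <- !is.na(lm_obj$y) & !is.na(lm_obj$x)
  rho <- suppressWarnings(stats::cor(lm_obj$x[ok], lm_obj$y[ok],
                                     method = "spearman"))
  restricted_cache <- list()
  for (p_y in seq_len(L_max)) for (p_x in seq_len(L_max)) {
    d_b <- .design_at(lm_obj, p_y, p_x)
    if (d_b$n < ncol(d_b$X) + 5 || d_b$n - 1 - p_y - p_x <= 0) next
    f_b <- tryCatch(fit_pooled_ar(d_b), error = function(e) NULL)
    if (is.null(f_b)) next
    ckey <- sprintf("%d_%d", p_y, max(p_y, p_x))
    f_a <- restricted_cache[[ckey]]
    if (is.null(f_a)) {
      d_a <- d_b
      d_a$X <- d_b$X[, !grepl("^x_lag", colnames(d_b$X)), drop = FALSE]
      f_a <- tryCatch(fit_pooled_ar(d_a), error = function(e) NULL)
      if (is.null(f_a)) next
      restricted_cache[[ckey]] <- f_a
    }
    gs <- granger_sargent(f_a$rss, f_b$rss, p_x, p_y, f_b$n, form = form)
    pmat[p_x, p_y] <- gs$p_value
    adj[p_x, p_y] <- f_b$adj_r2
    nmat[p_x, p_y] <- f_b$n
    smat[p_x, p_y] <- if (sign_method == "spearman") {
      if (is.na(rho)) NA_character_ else if (rho >= 0) "+" else "-"
    } else {
      cs <- sum(f_b$coefficients[grepl("^x_lag", names(f_b$coefficients))])
      if (cs >= 0) "+" else "-"
    }
  }
  structure(list(y = y, x = x, L_max = L_max, p = pmat,
                 bin = matrix(.bin_p(pmat), L_max, L_max, dimnames = dn),
                 sign = smat, adj_r2 = adj, n = nmat,
                 autocorrelation = .track_acf(lm_obj),
                 spearman = rho, sign_method = sign_method, form = form),
            class = "sig_grid")
}

#' @export
print.sig_grid <- function(x, ...) {
  nsig <- sum(x$p < 0.05, na.rm = TRUE)
  nstrong <- sum(x$p < 1e-4, na.rm = TRUE)
  ncell <- sum(!is.na(x$p))
  cat(sprintf("Significance grid: %s -> %s (%dx%d)\n", x$x, x$y,
              x$L_max, x$L_max))
  cat(sprintf("%d/%d cells significant at 0.05, %d at 0.0001; sign %s (Spearman r_s = %.3f)\n",
              nsig, ncell, nstrong,
              names(sort(table(x$sign), decreasing = TRUE))[1],
              x$spearman))
  invisible(x)
}

#' @export
plot.sig_grid <- function(x, ...) {
  lev <- matrix(match(x$bin, .SIG_LABELS) - 1, x$L_max, x$L_max)
  sg <- ifelse(x$sign == "-", -1, 1)
  z <- lev * sg
  graphics::image(seq_len(x$L_max), seq_len(x$L_max), z,
                  zlim = c(-4, 4),
                  col = c(rev(grDevices::hcl.colors(4, "Blues")), "white",
                          grDevices::hcl.colors(4, "Reds", rev = TRUE)),
                  xlab = paste("lags of", x$x),
                  ylab = paste("lags of", x$y),
                  main = sprintf("%s -> %s", x$x, x$y), ...)
  invisible(x)
}
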