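# Feature-wise Box-Cox normalization with normalizability screening, and
# augmented Dickey-Fuller stationarity verification.

#' Box-Cox normalize a feature
#'
#' The power parameter lambda is chosen by profile maximum likelihood on a
#' grid over `[-3, 3]` (step 0.01); the transform is
#' `y = (x^lambda - 1)/lambda` (natural log at lambda = 0). Inputs are
#' shifted to positivity when needed (shift recorded). The transformed
#' values are standardized to zero mean and unit variance and screened for
#' normality with an Anderson-Darling test at `alpha`; features failing the
#' screen get verdict `"discarded"`.
#'
#' @param x Numeric values (>= 20 finite values required).
#' @param lambda_grid Candidate lambda grid.
#' @param alpha Normality-screen significance level (default 0.01).
#' @return Object of class `boxcox_result`: `lambda`, `shift`,
#'   `transformed` (standardized, `NA` kept in place), `mean`, `sd`,
#'   `normality_p`, `verdict`.
#' @export
#' @examples
#' r <- boxcox_normalize(rlnorm(500))
#' r$lambda  # near 0 for log-normal data
boxcox_normalize <- function(x, lambda_grid = seq(-3, 3, by = 0.01),
                             alpha = 0.01) {
  ok <- is.finite(x)
  xs <- x[ok]
  if (length(xs) < 20) stop("need >= 20 finite values")
  if (stats::sd(xs) == 0)
    return(structure(list(lambda = NA_real_, shift = 0, transformed = NULL,
                          mean = NA_real_, sd = NA_real_,
                          normality_p = NA_real_, verdict = "discarded",
                          reason = "constant input"),
                     class = "boxcox_result"))
  shift <- if (min(xs) <= 0) -min(xs) + 1e-6 * max(stats::sd(xs), 1e-12) else 0
  z <- xs + shift
  lz <- log(z)
  slz <- sum(lz)
  n <- length(z)
  ll <- vapply(lambda_grid, function(l) {
    y <- if (abs(l) < 1e-12) lz else (z^l - 1) / l
    v <- stats::var(y) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * slz
  }, numeric(1))
  lambda <- lambda_grid[which.max(ll)]
  y <- if (abs(lambda) < 1e-12) lz else (z^lambda - 1) / lambda
  mu <- mean(y); sdy <- stats::sd(y)
  ystd <- (y - mu) / sdy
  p <- tryCatch(nortest::ad.test(ystd)$p.value, error = function(e) 0)
  out <- rep(NA_real_, length(x))
  out[ok] <- ystd
  structure(list(lambda = lambda, shift = shift, transformed = out,
                 mean = mu, sd = sdy, normality_p = p,
                 verdict = if (p >= alpha) "normalizable" else "discarded"),
            class = "boxcox_result")
}

#' @export
print.boxcox_result <- function(x, ...) {
  cat(sprintf("Box-Cox fit: lambda = %s, shift = %.4g, verdict = %s (AD p = %.3g)\n",
              format(x$lambda), x$shift, x$verdict,
              if (is.na(x$normality_p)) NA else x$normality_p))
  invisible(x)
}

#' Box-Cox normalize every feature of a panel
#'
#' Each feature is normalized independently; features whose transformed
#' distribution still fails the normality screen (non-normalizable) are
#' excluded from the returned panel and listed, mirroring the supervised
#' discard step that precedes regression modeling.
#'
#' @param panel Feature panel (key columns `condition`, `repeat_id`,
#'   `cell_id`, `frame` plus feature columns).
#' @param features Feature columns to normalize (default: all non-key).
#' @param alpha Normality-screen level.
#' @param keep Features to retain regardless of the screen (manual
#'   override list).
#' @return List: `panel` (normalized, discarded features dropped),
#'   `transforms` (named list of `boxcox_result`), `discarded` (character).
#' @export
normalize_panel <- function(panel, features = NULL, alpha = 0.01,
                            keep = character(0)) {
  keycols <- c("condition", "repeat_id", "cell_id", "frame")
  if (is.null(features)) features <- setdiff(names(panel), keycols)
  stopifnot(length(features) > 0, all(features %in% names(panel)))
  transforms <- list()
  discarded <- character(0)
  for (f in features) {
    r <- tryCatch(boxcox_normalize(panel[[f]], alpha = alpha),
                  error = function(e) structure(
                    list(lambda = NA_real_, verdict = "discarded",
                         transformed = NULL, reason = conditionMessage(e)),
                    class = "boxcox_result"))
    transforms[[f]] <- r
    if (r$verdict == "discarded" && !(f %in% keep)) {
      discarded <- c(discarded, f)
      panel[[f]] <- NULL
    } else if (!is.null(r$transformed)) {
      panel[[f]] <- r$transformed
    }
  }
  if (length(discarded) == length(features))
    stop("all features discarded as non-normalizable")
  list(panel = panel, transforms = transforms, discarded = discarded)
}

# MacKinnon response-surface critical values, constant-only regression.
.ADF_CRIT <- list(
  "0.01" = c(-3.43035, -6.5393, -16.786),
  "0.05" = c(-2.86154, -2.8903, -4.234),
  "0.10" = c(-2.56677, -1.5384, -2.809))

#' Augmented Dickey-Fuller unit-root test
#'
#' Constant-only ADF regression
#' `diff(x)_t = a + g x_{t-1} + sum phi_i diff(x)_{t-i} + e_t` with the
#' augmentation order chosen by AIC up to `max_lags`. The null of a unit
#' root is rejected when the t-statistic on `g` falls below the
#' finite-sample critical value (response-surface interpolation); an
#' approximate p-value is interpolated between tabulated levels.
#'
#' @param x Numeric time series (single contiguous track).
#' @param max_lags Maximal augmentation order; default
#'   `trunc((length(x) - 1)^(1/3))`.
#' @return List: `statistic`, `lags`, `p_approx`, and logical rejections
#'   `reject_01`, `reject_05`, `reject_10`.
#' @export
adf_test <- function(x, max_lags = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0)
    return(list(statistic = NA_real_, lags = NA_integer_, p_approx = NA_real_,
                reject_01 = NA, reject_05 = NA, reject_10 = NA))
  if (is.null(max_lags)) max_lags <- max(0L, trunc((n - 1)^(1/3)))
  dx <- diff(x)
  fit_one <- function(k) {
    t0 <- k + 1
    y <- dx[t0:(n - 1)]
    X <- cbind(1, x[t0:(n - 1)])
    if (k > 0)
      for (i in seq_len(k)) X <- cbind(X, dx[(t0 - i):(n - 1 - i)])
    if (nrow(X) <= ncol(X) + 1) return(NULL)
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    m <- length(y)
    list(aic = m * log(rss / m) + 2 * ncol(X), fit = f, rss = rss,
         m = m, p = ncol(X), k = k)
  }
  cands <- Filter(Negate(is.null), lapply(0:max_lags, fit_one))
  if (!length(cands))
    return(list(statistic = NA_real_, lags = NA_integer_, p_approx = NA_real_,
                reject_01 = NA, reject_05 = NA, reject_10 = NA))
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "aic"))]]
  sigma2 <- best$rss / (best$m - best$p)
  XtX <- crossprod(cbind(1, x[(best$k + 1):(n - 1)],
                         if (best$k > 0) sapply(seq_len(best$k), function(i)
                           dx[(best$k + 1 - i):(n - 1 - i)])))
  vc <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(vc))
    return(list(statistic = NA_real_, lags = best$k, p_approx = NA_real_,
                reject_01 = NA, reject_05 = NA, reject_10 = NA))
  se <- sqrt(sigma2 * vc[2, 2])
  stat <- best$fit$coefficients[2] / se
  Tn <- best$m
  crit <- vapply(.ADF_CRIT, function(b) b[1] + b[2] / Tn + b[3] / Tn^2,
                 numeric(1))
  lv <- c(0.01, 0.05, 0.10)
  p_approx <- if (stat <= crit[1]) 0.005
  else if (stat >= crit[3]) {
    # extrapolate toward the near-certain-null region
    min(0.99, 0.10 + (stat - crit[3]) * 0.25)
  } else stats::approx(crit, lv, xout = stat)$y
  list(statistic = unname(stat), lags = best$k, p_approx = p_approx,
       reject_01 = stat < crit[1], reject_05 = stat < crit[2],
       reject_10 = stat < crit[3])
}

#' Verify per-feature stationarity across cell tracks
#'
#' Applies the ADF test per feature on every sufficiently long cell track
#' and calls the feature stationary when the unit root is rejected at
#' `alpha = 0.05` for at least `min_fraction` of the tested tracks.
#' Non-stationary features are flagged; analysis proceeds with a warning
#' (the check is verification, not a gate).
#'
#' @param panel Feature panel.
#' @param features Feature columns to test (default all non-key).
#' @param min_length Minimal track length tested (default 10).
#' @param min_fraction Required rejection fraction (default 0.8).
#' @return Data frame: feature, n_tracks_tested, fraction_rejecting,
#'   verdict in `{"stationary", "non-stationary", "untested"}`.
#' @export
check_stationarity <- function(panel, features = NULL, min_length = 10,
                               min_fraction = 0.8) {
  keycols <- c("condition", "repeat_id", "cell_id", "frame")
  if (is.null(features)) features <- setdiff(names(panel), keycols)
  key <- .track_key(panel)
  ord <- order(key, panel$frame)
  panel <- panel[ord, , drop = FALSE]
  groups <- split(seq_len(nrow(panel)), key[ord])
  groups <- groups[vapply(groups, length, integer(1)) >= min_length]
  out <- lapply(features, function(f) {
    rej <- vapply(groups, function(idx) {
      v <- panel[[f]][idx]
      if (anyNA(v) || stats::sd(v) == 0) return(NA)
      adf_test(v)$reject_05
    }, logical(1))
    rej <- rej[!is.na(rej)]
    n <- length(rej)
    frac <- if (n) mean(rej) else NA_real_
    verdict <- if (!n) "untested"
               else if (frac >= min_fraction) "stationary" else "non-stationary"
    data.frame(feature = f, n_tracks_tested = n,
               fraction_rejecting = frac, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(res$verdict == "non-stationary"))
    warning(sprintf("non-stationary features flagged: %s",
                    paste(res$feature[res$verdict == "non-stationary"],
                          collapse = ", ")))
  res
}
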