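# Subpopulation discovery: SVD-based PCA, randomly seeded EM fitting of
# Gaussian mixtures with full covariances, and AIC model selection over
# K in 2..8.

#' Principal component analysis via singular value decomposition
#'
#' @param x Numeric matrix (observations x features); centered per feature
#'   before decomposition (and optionally scaled).
#' @param scale Scale features to unit variance first (default FALSE).
#' @return List: `scores` (n x d), `loadings` (orthonormal columns),
#'   `sdev`, `variance_fraction` (non-increasing, sums to 1).
#' @export
pca_svd <- function(x, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations")
  xc <- scale(x, center = TRUE, scale = scale)
  sv <- svd(xc)
  d2 <- sv$d^2
  list(scores = sv$u %*% diag(sv$d, length(sv$d)),
       loadings = sv$v,
       sdev = sv$d / sqrt(nrow(x) - 1),
       variance_fraction = d2 / sum(d2))
}

#' Number of components reaching a variance target
#'
#' @param variance_fraction Output of [pca_svd()].
#' @param target Cumulative variance target (default 0.85).
#' @return Smallest component count whose cumulative variance fraction
#'   reaches `target`.
#' @export
n_components_for_variance <- function(variance_fraction, target = 0.85) {
  which(cumsum(variance_fraction) >= target)[1]
}

# log multivariate normal density via Cholesky
.dmvnorm_log <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- length(mu)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - d / 2 * log(2 * pi)
}

#' Fit a Gaussian mixture by the EM algorithm
#'
#' Full-covariance Gaussian mixture fitted by expectation-maximization,
#' initiated by random seeding (random observations as means, pooled
#' covariance) to relieve the locking effect of deterministic
#' initialization. Convergence when the log-likelihood improves by less
#' than `tol` (default 1e-8) or after `max_iter` (500) iterations.
#' Singular component covariances are ridge-regularized (1e-6) and flagged.
#'
#' @param x Numeric matrix of observations (e.g. PCA scores).
#' @param k Number of components (>= 1; n >= 10k required).
#' @param seed Integer seed for the random initialization.
#' @param tol,max_iter Convergence controls.
#' @param aic_k_param AIC penalty accounting: `"free"` (default) counts all
#'   free parameters, `(K-1) + K d + K d(d+1)/2`; `"groups"` penalizes by
#'   the number of groups only (`k = K`).
#' @return Object of class `cmac_mixture`: `k`, `labels`, `means` (k x d),
#'   `covariances` (list), `weights`, `loglik`, `loglik_trace`, `aic`,
#'   `n_params`, `regularized`.
#' @export
fit_mixture_em <- function(x, k, seed = 1, tol = 1e-8, max_iter = 500,
                           aic_k_param = c("free", "groups")) {
  aic_k_param <- match.arg(aic_k_param)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  stopifnot(k >= 1, n >= 10 * k)
  set.seed(seed)
  # random seeding, distance-weighted: the first mean is a random
  # observation, each next one drawn with probability proportional to the
  # squared distance to the nearest mean already chosen. This keeps the
  # seeding random (relieving the locking effect of deterministic
  # initialization) while spreading components over separated modes.
  mu <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(mu) < k) {
    d2 <- apply(x, 1, function(r) min(colSums((t(mu) - r)^2)))
    mu <- rbind(mu, x[sample.int(n, 1, prob = pmax(d2, 1e-12)), ])
  }
  fit <- .em_gmm_cpp(x, mu, tol, as.integer(max_iter), 1e-6)
  labels <- max.col(fit$responsibilities)
  n_params <- if (aic_k_param == "free")
    (k - 1) + k * d + k * d * (d + 1) / 2 else k
  sig <- lapply(seq_len(k), function(j) fit$covariances[, , j])
  # The mixture likelihood is unbounded: a component collapsing onto a
  # handful of points drives its covariance singular and the log-likelihood
  # to infinity. Such solutions are spurious maxima, not models; flag them
  # so model selection can reject the fit.
  nk <- colSums(fit$responsibilities)
  floor_eig <- 1e-4 * mean(diag(stats::cov(x)))
  min_eig <- vapply(sig, function(s)
    min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), numeric(1))
  degenerate <- any(nk < d + 1) || any(min_eig < floor_eig)
  structure(list(k = k, labels = labels, means = fit$means,
                 covariances = sig, weights = as.vector(fit$weights),
                 loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                 aic = 2 * n_params - 2 * fit$loglik, n_params = n_params,
                 regularized = fit$regularized, degenerate = degenerate,
                 responsibilities = fit$responsibilities),
            class = "cmac_mixture")
}

#' @export
print.cmac_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, logLik = %.2f, AIC = %.2f%s\n",
              x$k, x$loglik, x$aic,
              if (x$regularized) " (ridge-regularized)" else ""))
  cat("component weights:", paste(sprintf("%.3f", x$weights), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
logLik.cmac_mixture <- function(object, ...)
  structure(object$loglik, df = object$n_params, class = "logLik")

#' @export
plot.cmac_mixture <- function(x, data, dims = c(1, 2), ...) {
  data <- as.matrix(data)
  graphics::plot(data[, dims[1]], data[, dims[2]], col = x$labels,
                 pch = 16, cex = 0.6, xlab = paste("dim", dims[1]),
                 ylab = paste("dim", dims[2]),
                 main = sprintf("Gaussian mixture, K = %d", x$k), ...)
  graphics::points(x$means[, dims[1]], x$means[, dims[2]], pch = 3, cex = 2,
                   lwd = 2)
  invisible(x)
}

#' Select the number of subpopulations by AIC
#'
#' For each K in `k_range` (the search grid is 2..8), the mixture is fit
#' `restarts` times from random seedings and the best (lowest-AIC) fit is
#' kept; the K minimizing AIC is selected. The final assignment is then
#' refit with `final_restarts` random seedings (100 by default) at the
#' selected K.
#'
#' @param x Observation matrix (e.g. retained principal-component scores).
#' @param k_range Candidate component counts (default `2:8`).
#' @param restarts Random restarts per K (default 10).
#' @param final_restarts Restarts for the final assignment (default 100;
#'   0 skips the refit and returns the selection-stage fit).
#' @param seed Master seed.
#' @param ... Passed to [fit_mixture_em()].
#' @return List: `best_k`, `aic_curve` (data frame K x AIC), `fit`
#'   (the final `cmac_mixture`).
#' @export
select_n_subpopulations <- function(x, k_range = 2:8, restarts = 10,
                                    final_restarts = 100, seed = 1, ...) {
  stopifnot(length(k_range) >= 1)
  seed <- abs(as.integer(seed)) %% 1000000L
  aics <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    best <- best_any <- NULL
    for (r in seq_len(restarts)) {
      f <- fit_mixture_em(x, k, seed = seed * 1000L + k * 101L + r, ...)
      if (is.null(best_any) || f$aic < best_any$aic) best_any <- f
      if (!f$degenerate && (is.null(best) || f$aic < best$aic)) best <- f
    }
    if (is.null(best)) best <- best_any   # all restarts degenerate
    aics[i] <- best$aic
    fits[[i]] <- best
  }
  best_i <- which.min(aics)
  best_k <- k_range[best_i]
  fit <- fits[[best_i]]
  if (final_restarts > 0) {
    for (r in seq_len(final_restarts)) {
      f <- fit_mixture_em(x, best_k, seed = seed * 1000L + 900000L + r, ...)
      if (!f$degenerate && f$aic < fit$aic) fit <- f
    }
  }
  list(best_k = best_k,
       aic_curve = data.frame(k = k_range, aic = aics), fit = fit)
}
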