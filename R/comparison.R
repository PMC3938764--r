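# Multivariate comparison of defined cell subpopulations: canonical variate
# analysis, pairwise Mahalanobis distances, single-linkage clustering of
# group means, MANOVA with Wilks' test, two-sample KS tests and Gaussian
# KDE.

.group_scatter <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  k <- nlevels(labels)
  d <- ncol(x)
  n <- nrow(x)
  gm <- rowsum(x, labels) / as.vector(table(labels))
  grand <- colMeans(x)
  W <- matrix(0, d, d)
  for (g in levels(labels)) {
    xc <- sweep(x[labels == g, , drop = FALSE], 2, gm[g, ])
    W <- W + crossprod(xc)
  }
  B <- crossprod(sweep(gm, 2, grand) * sqrt(as.vector(table(labels))))
  list(W = W, B = B, group_means = gm, n = n, k = k, d = d,
       counts = as.vector(table(labels)), levels = levels(labels))
}

#' Canonical variate analysis
#'
#' Directions maximizing between-group relative to within-group variance,
#' from the eigendecomposition of `solve(W) %*% B` built on the
#' between-group and within-group covariance matrices. A singular
#' within-group covariance is ridge-regularized (1e-6) and flagged; with
#' fewer observations than `d + 2` per group the analysis is computed on a
#' PCA-reduced dimension and flagged.
#'
#' @param x Observation matrix.
#' @param labels Group labels (>= 2 groups).
#' @return Object of class `cva_fit`: `vectors` (canonical vectors, columns
#'   ordered by eigenvalue), `scores`, `eigenvalues`,
#'   `between_fraction` (fraction of between-group variation per vector),
#'   `group_means`, flags `regularized`, `reduced_dim`.
#' @export
cva <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  reduced <- NULL
  min_n <- min(table(labels))
  if (min_n < ncol(x) + 2) {
    # reduce to a dimension the smallest group can support
    target <- max(1, min_n - 2)
    p <- pca_svd(x)
    reduced <- p$loadings[, seq_len(target), drop = FALSE]
    x <- as.matrix(scale(x, center = TRUE, scale = FALSE)) %*% reduced
  }
  gs <- .group_scatter(x, labels)
  Wc <- gs$W / (gs$n - gs$k)
  Bc <- gs$B / max(1, gs$k - 1)
  regularized <- FALSE
  ev_min <- min(eigen(Wc, symmetric = TRUE, only.values = TRUE)$values)
  if (!is.finite(ev_min) || ev_min < 1e-10) {
    Wc <- Wc + diag(1e-6, ncol(x))
    regularized <- TRUE
  }
  eg <- eigen(solve(Wc, Bc))
  ord <- order(Re(eg$values), decreasing = TRUE)
  vals <- pmax(Re(eg$values[ord]), 0)
  vecs <- Re(eg$vectors[, ord, drop = FALSE])
  vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), `/`)
  n_cv <- min(gs$k - 1, ncol(x))
  vals <- vals[seq_len(n_cv)]
  vecs <- vecs[, seq_len(n_cv), drop = FALSE]
  scores <- sweep(x, 2, colMeans(x)) %*% vecs
  structure(list(vectors = vecs, scores = scores, eigenvalues = vals,
                 between_fraction = if (sum(vals) > 0) vals / sum(vals)
                                    else rep(0, length(vals)),
                 group_means = gs$group_means, levels = gs$levels,
                 regularized = regularized, reduced_dim = reduced),
            class = "cva_fit")
}

#' @export
print.cva_fit <- function(x, ...) {
  cat(sprintf("CVA: %d canonical vector(s); CV1 carries %.1f%% of between-group variation%s\n",
              length(x$eigenvalues), 100 * x$between_fraction[1],
              if (x$regularized) " (ridge-regularized)" else ""))
  invisible(x)
}

#' @export
plot.cva_fit <- function(x, labels = NULL, ...) {
  s <- x$scores
  if (ncol(s) == 1) s <- cbind(s, stats::runif(nrow(s), -0.2, 0.2))
  graphics::plot(s[, 1], s[, 2], col = if (is.null(labels)) 1
                 else as.integer(as.factor(labels)),
                 pch = 16, cex = 0.6, xlab = "CV1", ylab = "CV2", ...)
  invisible(x)
}

#' Pairwise Mahalanobis distances between groups
#'
#' `D(a, b) = sqrt((mu_a - mu_b)' S^-1 (mu_a - mu_b))` with `S` the pooled
#' within-group covariance (ridge-regularized if singular). Groups of size
#' < 2 are excluded and flagged.
#'
#' @param x Observation matrix.
#' @param labels Group labels.
#' @return Symmetric distance matrix with zero diagonal; attribute
#'   `excluded` lists dropped groups.
#' @export
mahalanobis_pairwise <- function(x, labels) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  excluded <- names(sizes)[sizes < 2]
  keep <- !(labels %in% excluded)
  x <- as.matrix(x)[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  gs <- .group_scatter(x, labels)
  S <- gs$W / (gs$n - gs$k)
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (!is.finite(ev) || ev < 1e-10) S <- S + diag(1e-6, ncol(x))
  Sinv <- solve(S)
  k <- gs$k
  D <- matrix(0, k, k, dimnames = list(gs$levels, gs$levels))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a < b) {
      dm <- gs$group_means[a, ] - gs$group_means[b, ]
      D[a, b] <- D[b, a] <- sqrt(drop(t(dm) %*% Sinv %*% dm))
    }
  }
  attr(D, "excluded") <- excluded
  D
}

#' Single-linkage clustering of group mean vectors
#'
#' Agglomerative hierarchical clustering of the per-group mean vectors,
#' subject to the shortest distance with the Euclidean metric.
#'
#' @param x Observation matrix (e.g. principal-component scores).
#' @param labels Group labels (>= 2 groups).
#' @return An [stats::hclust] tree over the group means.
#' @export
hcluster_group_means <- function(x, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  gm <- rowsum(as.matrix(x), labels) / as.vector(table(labels))
  stats::hclust(stats::dist(gm, method = "euclidean"), method = "single")
}

#' MANOVA with Wilks' lambda
#'
#' `Lambda = det(W) / det(B + W)`; significance from Bartlett's chi-square
#' approximation, `-(n - 1 - (d + K)/2) log(Lambda)` on `d (K - 1)` degrees
#' of freedom.
#'
#' @param x Observation matrix; requires `n > d + K`.
#' @param labels Group labels.
#' @return List: `wilks_lambda`, `chisq`, `df`, `p_value`.
#' @export
manova_wilks <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  gs <- .group_scatter(x, labels)
  if (gs$n <= gs$d + gs$k) stop("need n > d + K observations")
  dW <- det(gs$W)
  dT <- det(gs$B + gs$W)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0 || dW <= 0)
    stop("singular scatter matrix: non-positive determinant")
  lambda <- dW / dT
  chisq <- -(gs$n - 1 - (gs$d + gs$k) / 2) * log(lambda)
  df <- gs$d * (gs$k - 1)
  list(wilks_lambda = lambda, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

# Kolmogorov-Smirnov critical coefficients c(alpha)
.KS_COEF <- c("0.1" = 1.224, "0.05" = 1.358, "0.025" = 1.48,
              "0.01" = 1.628, "0.005" = 1.731, "0.001" = 1.949)

#' Two-sample Kolmogorov-Smirnov test with critical-value decision
#'
#' `D = sup |Fx - Fy|` over the pooled sample; the decision compares `D`
#' with the asymptotic critical value
#' `c(alpha) sqrt((n + m) / (n m))` at the requested level (5% by
#' default).
#'
#' @param x,y Samples (each >= 10 values).
#' @param alpha Significance level; one of 0.1, 0.05, 0.025, 0.01, 0.005,
#'   0.001.
#' @return List: `D`, `p_value`, `critical`, `reject`.
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 10, length(y) >= 10)
  coef <- .KS_COEF[as.character(alpha)]
  if (is.na(coef)) stop("unsupported alpha for the critical-value table")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  crit <- unname(coef) * sqrt((length(x) + length(y)) /
                                (length(x) * length(y)))
  list(D = unname(kt$statistic), p_value = kt$p.value, critical = crit,
       reject = unname(kt$statistic) > crit)
}

#' Gaussian kernel density estimate with fixed bandwidth
#'
#' @param x Sample (a single point is allowed as a special case).
#' @param bandwidth Fixed kernel standard deviation (> 0).
#' @param n_grid Evaluation grid size.
#' @return List: `x` (grid), `y` (density, integrates to 1 on the grid),
#'   `fun` (interpolating density function).
#' @export
kde_gaussian <- function(x, bandwidth, n_grid = 1024) {
  if (!(is.numeric(bandwidth) && bandwidth > 0))
    stop("bandwidth must be > 0")
  grid <- seq(min(x) - 6 * bandwidth, max(x) + 6 * bandwidth,
              length.out = n_grid)
  # exact kernel sum (chunked): the FFT binning of stats::density() is too
  # coarse for the 1e-6 normalization contract
  y <- numeric(n_grid)
  for (chunk in split(seq_len(n_grid), ceiling(seq_len(n_grid) / 128))) {
    y[chunk] <- colMeans(matrix(
      stats::dnorm(outer(x, grid[chunk], "-"), sd = bandwidth),
      nrow = length(x)))
  }
  list(x = grid, y = y,
       fun = stats::approxfun(grid, y, yleft = 0, yright = 0))
}
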