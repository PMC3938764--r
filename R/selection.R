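# Feature selection: CVA on speed quintiles, elastic-net regression-path
# ranking, and the global Spearman correlation map.

#' Rank organizational features by CVA on speed quintiles
#'
#' Cells are stratified into quintiles of Instantaneous Cell Speed; the
#' slowest (S1, 1-20%) and fastest (S5, 81-100%) quintiles are compared by
#' two-group CVA over the organizational features, and features are ranked
#' by the absolute loading coefficient on the first canonical vector.
#'
#' @param panel Normalized feature panel.
#' @param response Response feature (default Instantaneous Cell Speed).
#' @param features Organizational features (default: all non-key columns
#'   except the response).
#' @param quantiles Lower/upper quintile boundaries (default `c(0.2, 0.8)`).
#' @return List: `ranking` (data frame feature, loading, abs_loading, in
#'   rank order), `cv1_between_fraction`, `n_slow`, `n_fast`, `cva`.
#' @export
cva_rank_features <- function(panel, response = "Instantaneous Cell Speed",
                              features = NULL, quantiles = c(0.2, 0.8)) {
  keycols <- c("condition", "repeat_id", "cell_id", "frame")
  if (is.null(features))
    features <- setdiff(names(panel), c(keycols, response))
  y <- panel[[response]]
  ok <- stats::complete.cases(panel[, c(response, features)])
  y <- y[ok]
  x <- as.matrix(panel[ok, features, drop = FALSE])
  q <- stats::quantile(y, quantiles)
  grp <- ifelse(y <= q[1], "S1", ifelse(y > q[2], "S5", NA))
  sel <- !is.na(grp)
  if (min(table(grp[sel])) < 30)
    warning("a speed quintile group has fewer than 30 observations")
  fit <- cva(x[sel, , drop = FALSE], grp[sel])
  loading <- if (is.null(fit$reduced_dim)) fit$vectors[, 1]
             else drop(fit$reduced_dim %*% fit$vectors[, 1])
  rk <- data.frame(feature = features, loading = loading,
                   abs_loading = abs(loading), stringsAsFactors = FALSE)
  rk <- rk[order(-rk$abs_loading), ]
  rownames(rk) <- NULL
  list(ranking = rk, cv1_between_fraction = fit$between_fraction[1],
       n_slow = sum(grp[sel] == "S1"), n_fast = sum(grp[sel] == "S5"),
       cva = fit)
}

#' Elastic-net regression path ranking
#'
#' Fits the elastic-net coefficient path for Instantaneous Cell Speed on
#' the organizational background features over a decreasing penalty grid.
#' At each iteration (penalty level) the adjusted coefficient of
#' determination `1 - (1 - R^2)(n - 1)/(n - p - 1)` is computed from the
#' elastic-net residuals with `p` the support size; the optimum is the
#' iteration maximizing adjusted R-squared and features are ranked by
#' absolute coefficient there. The elastic net is used for its grouping
#' effect: coefficients of multicollinear features are not shrunk
#' independently.
#'
#' @param panel Normalized feature panel.
#' @param response Response feature name.
#' @param features Background features.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param nlambda Penalty grid size (default 100, log-spaced, decreasing).
#' @return Object of class `en_path`: `path` (data frame: iteration,
#'   lambda, n_nonzero, r2, adj_r2), `coefficients` (features x
#'   iterations), `opt_iteration`, `ranking` (data frame in rank order),
#'   `truncated` (TRUE when n <= p stopped the path before saturation).
#' @export
elastic_net_rank <- function(panel, response = "Instantaneous Cell Speed",
                             features = NULL, alpha = 0.5, nlambda = 100) {
  keycols <- c("condition", "repeat_id", "cell_id", "frame")
  if (is.null(features))
    features <- setdiff(names(panel), c(keycols, response))
  ok <- stats::complete.cases(panel[, c(response, features)])
  y <- panel[[response]][ok]
  x <- as.matrix(panel[ok, features, drop = FALSE])
  n <- length(y)
  fit <- glmnet::glmnet(x, y, alpha = alpha, nlambda = nlambda,
                        standardize = FALSE)
  beta <- as.matrix(fit$beta)
  lambda <- fit$lambda
  n_iter <- length(lambda)
  pred <- stats::predict(fit, newx = x)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - colSums((y - pred)^2) / tss
  p_nz <- apply(beta != 0, 2, sum)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / pmax(1, n - p_nz - 1)
  truncated <- any(n <= p_nz)
  usable <- which(n > p_nz + 1)
  opt <- usable[which.max(adj_r2[usable])]
  rk <- data.frame(feature = features, coefficient = beta[, opt],
                   abs_coefficient = abs(beta[, opt]),
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$abs_coefficient), ]
  rownames(rk) <- NULL
  structure(list(path = data.frame(iteration = seq_len(n_iter),
                                   lambda = lambda, n_nonzero = p_nz,
                                   r2 = r2, adj_r2 = adj_r2),
                 coefficients = beta, opt_iteration = opt, ranking = rk,
                 alpha = alpha, truncated = truncated, n = n),
            class = "en_path")
}

#' @export
print.en_path <- function(x, ...) {
  cat(sprintf("Elastic-net path (alpha = %g): %d iterations, optimum at iteration %d (adjusted R2 = %.3f, %d nonzero)\n",
              x$alpha, nrow(x$path), x$opt_iteration,
              x$path$adj_r2[x$opt_iteration],
              x$path$n_nonzero[x$opt_iteration]))
  cat("top features:\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' @export
plot.en_path <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$path)), t(x$coefficients), type = "l",
                    lty = 1, xlab = "iteration (decreasing penalty)",
                    ylab = "coefficient", ...)
  graphics::abline(v = x$opt_iteration, col = "grey40", lty = 2)
  invisible(x)
}

#' Global Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations between all features, with
#' pairwise-complete handling of missing values and average ranks for
#' ties. Constant features give missing rows/columns and are flagged.
#'
#' @param panel Feature panel.
#' @param features Feature columns (default all non-key).
#' @param min_pairs Minimal complete observations per pair (default 10;
#'   sparser pairs are set to `NA`).
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `constant_features` names flagged features.
#' @export
spearman_matrix <- function(panel, features = NULL, min_pairs = 10) {
  keycols <- c("condition", "repeat_id", "cell_id", "frame")
  if (is.null(features)) features <- setdiff(names(panel), keycols)
  x <- as.matrix(panel[, features, drop = FALSE])
  constant <- features[apply(x, 2, function(v)
    stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v)))]
  rs <- suppressWarnings(stats::cor(x, method = "spearman",
                                    use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(x))
  rs[npair < min_pairs] <- NA
  diag(rs) <- 1
  rs[features %in% constant, ] <- NA
  rs[, features %in% constant] <- NA
  attr(rs, "constant_features") <- constant
  rs
}

#' Ranked-value scatter table for a feature pair
#'
#' Rank-transformed co-distribution of two features (the ranked-value
#' scatter used to visualize Spearman relationships).
#'
#' @param panel Feature panel.
#' @param f1,f2 Feature names.
#' @return Data frame with columns `rank_f1`, `rank_f2` plus the raw
#'   values.
#' @export
ranked_pair <- function(panel, f1, f2) {
  ok <- stats::complete.cases(panel[, c(f1, f2)])
  v1 <- panel[[f1]][ok]; v2 <- panel[[f2]][ok]
  data.frame(rank_f1 = rank(v1), rank_f2 = rank(v2),
             value_f1 = v1, value_f2 = v2)
}
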