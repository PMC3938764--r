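# Edge inference from significance grids, reciprocal testing, causal-graph
# assembly, chain verification and cross-condition plasticity comparison.

#' Edge-inference criterion
#'
#' Operationalizes "robust and ordered" significance patterns: an edge is
#' declared when (a) at least `frac_sig` of grid cells are significant at
#' `alpha`, (b) at least `frac_strong` are significant at `strong_alpha`,
#' and (c) all significant cells share one sign.
#'
#' @param frac_sig Minimal fraction of cells significant at `alpha`
#'   (default 0.6).
#' @param frac_strong Minimal fraction significant at `strong_alpha`
#'   (default 0.25).
#' @param alpha,strong_alpha Significance thresholds (0.05 and 0.0001).
#' @param require_sign_consistency Enforce criterion (c) (default TRUE).
#' @return List of class `edge_criterion`.
#' @export
edge_criterion <- function(frac_sig = 0.6, frac_strong = 0.25,
                           alpha = 0.05, strong_alpha = 1e-4,
                           require_sign_consistency = TRUE) {
  structure(list(frac_sig = frac_sig, frac_strong = frac_strong,
                 alpha = alpha, strong_alpha = strong_alpha,
                 require_sign_consistency = require_sign_consistency),
            class = "edge_criterion")
}

#' Decide a directed causal edge from a significance grid
#'
#' @param grid A [significance_grid()] result (background -> response).
#' @param criterion An [edge_criterion()].
#' @return Object of class `edge_decision`: `declared`, `sign` (sign of
#'   the significant cells, `NA` when none), `frac_sig`, `frac_strong`,
#'   `sign_consistent`, `checks` (which sub-criteria passed), and the
#'   source/target names.
#' @export
infer_edge <- function(grid, criterion = edge_criterion()) {
  stopifnot(inherits(grid, "sig_grid"))
  p <- grid$p[!is.na(grid$p)]
  sg <- grid$sign[!is.na(grid$p)]
  ncell <- length(p)
  if (ncell == 0)
    return(structure(list(declared = FALSE, sign = NA_character_,
                          frac_sig = NA_real_, frac_strong = NA_real_,
                          sign_consistent = NA, checks = c(a = FALSE,
                                                           b = FALSE,
                                                           c = FALSE),
                          source = grid$x, target = grid$y,
                          criterion = criterion),
                     class = "edge_decision"))
  sig <- p < criterion$alpha
  frac_sig <- mean(sig)
  frac_strong <- mean(p < criterion$strong_alpha)
  signs <- unique(sg[sig & !is.na(sg)])
  sign_consistent <- length(signs) <= 1
  checks <- c(a = frac_sig >= criterion$frac_sig,
              b = frac_strong >= criterion$frac_strong,
              c = sign_consistent || !criterion$require_sign_consistency)
  declared <- all(checks)
  structure(list(declared = declared,
                 sign = if (length(signs) == 1) signs else NA_character_,
                 frac_sig = frac_sig, frac_strong = frac_strong,
                 sign_consistent = sign_consistent, checks = checks,
                 source = grid$x, target = grid$y, criterion = criterion),
            class = "edge_decision")
}

#' @export
print.edge_decision <- function(x, ...) {
  cat(sprintf("%s -> %s: %s%s (%.0f%% sig at %.3g, %.0f%% at %.0e)\n",
              x$source, x$target,
              if (x$declared) "edge declared" else "no edge",
              if (x$declared) paste0(" (", x$sign, ")") else "",
              100 * x$frac_sig, x$criterion$alpha,
              100 * x$frac_strong, x$criterion$strong_alpha))
  invisible(x)
}

#' Reciprocal Granger analysis of a feature pair
#'
#' Causation is tested reciprocally: a grid for X -> Y (response Y) and a
#' grid for Y -> X (response X), each passed through the edge criterion.
#'
#' @param panel Feature panel.
#' @param x,y The two feature names.
#' @param L_max Maximal lag.
#' @param criterion An [edge_criterion()].
#' @param ... Passed to [significance_grid()].
#' @return Object of class `granger_reciprocal`: `grid_xy`, `grid_yx`,
#'   `edge_xy`, `edge_yx`, `classification` in
#'   `{"X->Y", "Y->X", "bidirectional", "none"}`.
#' @export
reciprocal_analysis <- function(panel, x, y, L_max = 10,
                                criterion = edge_criterion(), ...) {
  grid_xy <- significance_grid(panel, y = y, x = x, L_max = L_max, ...)
  grid_yx <- significance_grid(panel, y = x, x = y, L_max = L_max, ...)
  e_xy <- infer_edge(grid_xy, criterion)
  e_yx <- infer_edge(grid_yx, criterion)
  cls <- if (e_xy$declared && e_yx$declared) "bidirectional"
         else if (e_xy$declared) "X->Y"
         else if (e_yx$declared) "Y->X"
         else "none"
  structure(list(x = x, y = y, grid_xy = grid_xy, grid_yx = grid_yx,
                 edge_xy = e_xy, edge_yx = e_yx, classification = cls),
            class = "granger_reciprocal")
}

#' @export
print.granger_reciprocal <- function(x, ...) {
  cat(sprintf("Reciprocal Granger analysis of '%s' (X) and '%s' (Y): %s\n",
              x$x, x$y, x$classification))
  print(x$edge_xy); print(x$edge_yx)
  invisible(x)
}

#' Build a per-condition causal graph over a feature set
#'
#' Runs the reciprocal analysis for every unordered feature pair and
#' collects the declared directed, signed edges with their evidence grids.
#'
#' @param panel Feature panel of one condition.
#' @param features Feature names to wire (>= 2); pairs are all unordered
#'   combinations, or supply `pairs` directly.
#' @param pairs Optional data frame with columns `x`, `y` restricting the
#'   tested pairs.
#' @param condition Condition label stored on the graph.
#' @param L_max,criterion,... As in [reciprocal_analysis()].
#' @return Object of class `causal_graph`: `edges` (data frame: source,
#'   target, sign, frac_sig, frac_strong), `tests` (all reciprocal
#'   results), `features`, `condition`.
#' @export
causal_graph <- function(panel, features, pairs = NULL,
                         condition = "control", L_max = 10,
                         criterion = edge_criterion(), ...) {
  if (is.null(pairs)) {
    stopifnot(length(features) >= 2)
    cmb <- utils::combn(features, 2)
    pairs <- data.frame(x = cmb[1, ], y = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  tests <- list()
  edges <- list()
  for (i in seq_len(nrow(pairs))) {
    ra <- reciprocal_analysis(panel, pairs$x[i], pairs$y[i], L_max = L_max,
                              criterion = criterion, ...)
    tests[[sprintf("%s | %s", pairs$x[i], pairs$y[i])]] <- ra
    for (e in list(ra$edge_xy, ra$edge_yx)) {
      if (e$declared)
        edges[[length(edges) + 1]] <- data.frame(
          source = e$source, target = e$target, sign = e$sign,
          frac_sig = e$frac_sig, frac_strong = e$frac_strong,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
  else data.frame(source = character(0), target = character(0),
                  sign = character(0), frac_sig = numeric(0),
                  frac_strong = numeric(0), stringsAsFactors = FALSE)
  structure(list(edges = edges, tests = tests,
                 features = unique(c(pairs$x, pairs$y)),
                 condition = condition, criterion = criterion),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Causal graph [%s]: %d directed edge(s) over %d features\n",
              x$condition, nrow(x$edges), length(x$features)))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s (%s)\n", x$edges$source[i],
                  x$edges$target[i], x$edges$sign[i]))
  invisible(x)
}

#' @export
plot.causal_graph <- function(x, ...) {
  f <- x$features
  n <- length(f)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  px <- cos(th); py <- sin(th)
  graphics::plot(px, py, xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5),
                 pch = 16, axes = FALSE, xlab = "", ylab = "",
                 main = x$condition, ...)
  graphics::text(1.2 * px, 1.2 * py, f, cex = 0.7)
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges))) {
      a <- match(x$edges$source[i], f); b <- match(x$edges$target[i], f)
      graphics::arrows(px[a], py[a], px[b], py[b], length = 0.1,
                       col = if (x$edges$sign[i] == "-") "blue" else "red")
    }
  invisible(x)
}

#' Verify a causal chain through a graph
#'
#' Checks that each consecutive pair of the feature sequence is a declared
#' edge and reports the signs along the chain (positive links drawn as
#' arrows, negative as capped lines in the field's schematics).
#'
#' @param graph A [causal_graph()].
#' @param features Ordered feature sequence (>= 2).
#' @return List of class `causal_chain`: `links` (data frame: source,
#'   target, present, sign), `intact`, `broken_at` (index of the first
#'   missing link, `NA` if intact).
#' @export
assemble_chain <- function(graph, features) {
  stopifnot(inherits(graph, "causal_graph"), length(features) >= 2)
  links <- data.frame(source = features[-length(features)],
                      target = features[-1],
                      present = FALSE, sign = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(links))) {
    hit <- graph$edges$source == links$source[i] &
      graph$edges$target == links$target[i]
    if (any(hit)) {
      links$present[i] <- TRUE
      links$sign[i] <- graph$edges$sign[which(hit)[1]]
    }
  }
  broken <- which(!links$present)
  structure(list(links = links, intact = !length(broken),
                 broken_at = if (length(broken)) broken[1] else NA_integer_),
            class = "causal_chain")
}

#' @export
print.causal_chain <- function(x, ...) {
  cat(if (x$intact) "Intact causal chain:\n"
      else sprintf("Broken causal chain (first missing link at position %d):\n",
                   x$broken_at))
  for (i in seq_len(nrow(x$links)))
    cat(sprintf("  %s %s %s\n", x$links$source[i],
                if (!x$links$present[i]) "-x->"
                else if (identical(x$links$sign[i], "-")) "--|" else "-->",
                x$links$target[i]))
  invisible(x)
}

#' Compare causal graphs across conditions (wiring plasticity)
#'
#' Per directed feature pair, classifies the edge across conditions
#' relative to the first (reference) graph: `conserved` (declared
#' everywhere with one sign), `lost` (declared in the reference, missing
#' elsewhere), `gained` (absent in the reference, declared elsewhere),
#' `sign-inverted` (declared with opposing signs). Graphs over differing
#' feature sets are compared on the intersection and flagged.
#'
#' @param graphs Named list of [causal_graph()] objects (>= 2).
#' @return Object of class `plasticity_report`: `table` (data frame:
#'   source, target, per-condition sign columns, status), counts per
#'   status, `shared_features`, `feature_mismatch` flag.
#' @export
compare_conditions <- function(graphs) {
  stopifnot(length(graphs) >= 2)
  if (is.null(names(graphs)) || any(!nzchar(names(graphs))))
    names(graphs) <- vapply(graphs, `[[`, character(1), "condition")
  fsets <- lapply(graphs, `[[`, "features")
  shared <- Reduce(intersect, fsets)
  mismatch <- !all(vapply(fsets, function(f) setequal(f, shared), logical(1)))
  if (mismatch)
    warning("feature sets differ between conditions; comparing on the intersection")
  if (length(shared) < 2) stop("fewer than 2 shared features")
  cmb <- utils::combn(shared, 2)
  pairs <- rbind(data.frame(source = cmb[1, ], target = cmb[2, ]),
                 data.frame(source = cmb[2, ], target = cmb[1, ]))
  sign_of <- function(g, s, t) {
    hit <- g$edges$source == s & g$edges$target == t
    if (any(hit)) g$edges$sign[which(hit)[1]] else NA_character_
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    sg <- vapply(graphs, sign_of, character(1), pairs$source[i],
                 pairs$target[i])
    present <- !is.na(sg)
    if (!any(present)) next
    status <- if (length(unique(sg[present])) > 1) "sign-inverted"
              else if (all(present)) "conserved"
              else if (present[1]) "lost" else "gained"
    row <- data.frame(source = pairs$source[i], target = pairs$target[i],
                      stringsAsFactors = FALSE)
    for (nm in names(graphs)) row[[nm]] <- unname(sg[nm])
    row$status <- status
    rows[[length(rows) + 1]] <- row
  }
  tab <- if (length(rows)) do.call(rbind, rows)
  else data.frame(source = character(0), target = character(0),
                  status = character(0), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 counts = table(factor(tab$status,
                                       levels = c("conserved", "lost",
                                                  "gained", "sign-inverted"))),
                 shared_features = shared, feature_mismatch = mismatch),
            class = "plasticity_report")
}

#' @export
print.plasticity_report <- function(x, ...) {
  cat("Causal wiring plasticity report\n")
  print(x$counts)
  if (nrow(x$table)) print(x$table)
  invisible(x)
}
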