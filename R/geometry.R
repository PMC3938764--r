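# Polygon geometry helpers. Cell outlines are simple (non-self-intersecting)
# polygons in um, serialized as WKT POLYGON strings in the interchange CSVs.

#' Serialize a polygon to WKT
#'
#' @param xy Two-column matrix of vertex coordinates (um), open ring
#'   (first vertex not repeated).
#' @return A `POLYGON ((...))` WKT string.
#' @export
polygon_to_wkt <- function(xy) {
  xy <- rbind(xy, xy[1, , drop = FALSE])
  coords <- paste(sprintf("%.6g %.6g", xy[, 1], xy[, 2]), collapse = ", ")
  sprintf("POLYGON ((%s))", coords)
}

#' Parse a WKT POLYGON string
#'
#' @param wkt A `POLYGON ((x y, ...))` string (single outer ring).
#' @return Two-column matrix of vertices, closing vertex dropped.
#' @export
wkt_to_polygon <- function(wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\)\\s*$", "", body)
  parts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  xy <- do.call(rbind, lapply(parts, function(p) {
    p <- p[nzchar(p)]
    as.numeric(p[1:2])
  }))
  n <- nrow(xy)
  if (n > 1 && all(abs(xy[1, ] - xy[n, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  colnames(xy) <- c("x", "y")
  xy
}

# Shoelace signed area
.polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Polygon area, perimeter and center of area
#'
#' @param xy Vertex matrix (open ring).
#' @return List with `area` (um2), `perimeter` (um), `centroid`
#'   (length-2 numeric, the center of area).
#' @export
polygon_properties <- function(xy) {
  a <- .polygon_signed_area(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cross <- x * ys - xs * y
  cx <- sum((x + xs) * cross) / (6 * a)
  cy <- sum((y + ys) * cross) / (6 * a)
  per <- sum(sqrt((xs - x)^2 + (ys - y)^2))
  list(area = abs(a), perimeter = per, centroid = c(cx, cy))
}

# Second area moments about the centroid; returns the equivalent-ellipse
# major/minor axis lengths (full lengths, um) and orientation.
.polygon_axes <- function(xy) {
  pr <- polygon_properties(xy)
  xy <- sweep(xy, 2, pr$centroid)
  x <- xy[, 1]; y <- xy[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cross <- x * ys - xs * y
  sa <- .polygon_signed_area(xy)
  ixx <- sum((y^2 + y * ys + ys^2) * cross) / 12
  iyy <- sum((x^2 + x * xs + xs^2) * cross) / 12
  ixy <- sum((x * ys + 2 * x * y + 2 * xs * ys + xs * y) * cross) / 24
  if (sa < 0) { ixx <- -ixx; iyy <- -iyy; ixy <- -ixy }
  a <- abs(sa)
  # normalized central moments of the area distribution
  m <- matrix(c(iyy, -ixy, -ixy, ixx), 2, 2) / a
  ev <- eigen(m, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  # ellipse with matching second moments: semi-axis = 2*sqrt(eigenvalue)
  list(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each query point to the polygon outline
#' (segments, not just vertices).
#'
#' @param pts Two-column matrix of query points.
#' @param poly Vertex matrix (open ring).
#' @return Numeric vector of distances (um), one per query point.
#' @export
dist_to_polygon_edge <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  a <- poly
  b <- poly[c(2:nrow(poly), 1), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ap_x <- pts[i, 1] - a[, 1]
    ap_y <- pts[i, 2] - a[, 2]
    t <- (ap_x * ab[, 1] + ap_y * ab[, 2]) / pmax(len2, 1e-300)
    t <- pmin(pmax(t, 0), 1)
    dx <- ap_x - t * ab[, 1]
    dy <- ap_y - t * ab[, 2]
    out[i] <- sqrt(min(dx^2 + dy^2))
  }
  out
}

#' Standardized distance to the cell edge
#'
#' For a point P inside a cell with boundary dOmega and center of area C,
#' returns s = d(P, dOmega) / (d(P, dOmega) + |P - C|), so that s = 0 on the
#' cell edge and s = 1 at the center of area. Well defined for any simple
#' polygon.
#'
#' @param pts Two-column matrix of CMAC centroids.
#' @param poly Cell outline vertex matrix (open ring).
#' @return List with numeric vectors `standardized`, `d_edge`, `d_center`.
#' @export
standardized_edge_distance <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  ctr <- polygon_properties(poly)$centroid
  d_edge <- dist_to_polygon_edge(pts, poly)
  d_center <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  s <- ifelse(d_edge + d_center == 0, 1, d_edge / (d_edge + d_center))
  list(standardized = s, d_edge = d_edge, d_center = d_center)
}

# Star-convex polygon from a radial profile: ellipse-like base with
# low-order Fourier perturbation, used by the microscopy simulator.
.star_polygon <- function(center, r_base, elong, phi, fourier_amp, fourier_phase,
                          n_vertices = 36) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- r_base * (1 + elong * cos(2 * (th - phi)))
  if (length(fourier_amp)) {
    for (k in seq_along(fourier_amp))
      r <- r * (1 + fourier_amp[k] * cos((k + 2) * th + fourier_phase[k]))
  }
  r <- pmax(r, 0.05 * r_base)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}
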