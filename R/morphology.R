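# Polygon geometry and per-nucleus morphometry.
#
# All morphology descriptors are computed from the polygon itself (shoelace
# area, arc-length perimeter, area moments), not from a rasterized mask, so
# they are exact for the stored contour and invariant to translation and
# (up to vertex resampling) to rotation.

#' Polygon area (shoelace)
#' @param m ring matrix (columns x, y; closed or open).
#' @return positive area in px^2.
#' @export
polygon_area <- function(m) {
  m <- open_ring(m)
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Polygon perimeter (arc length)
#' @inheritParams polygon_area
#' @return perimeter in px.
#' @export
polygon_perimeter <- function(m) {
  m <- close_ring(m)
  sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
}

#' Polygon area centroid
#' @inheritParams polygon_area
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(m) {
  m <- open_ring(m)
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# central second area moments (mu20, mu02, mu11), normalized by area
polygon_moments <- function(m) {
  m <- open_ring(m)
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  s <- sign(a)
  c(mu20 = s * ixx / abs(a) - cx^2,
    mu02 = s * iyy / abs(a) - cy^2,
    mu11 = s * ixy / abs(a) - cx * cy)
}

MORPHOLOGY_NAMES <- c("area", "perimeter", "equivalent_diameter",
                      "major_axis", "minor_axis", "eccentricity",
                      "solidity", "extent", "circularity", "aspect_ratio")

#' Morphology descriptors of one nucleus
#'
#' Ten geometric descriptors of the nuclear contour: `area` (px^2),
#' `perimeter` (px), `equivalent_diameter` = 2*sqrt(area/pi) (px),
#' `major_axis`/`minor_axis` (px; full axis lengths of the ellipse with the
#' same second area moments), `eccentricity` in \[0, 1), `solidity` =
#' area / convex hull area, `extent` = area / bounding-box area,
#' `circularity` = 4*pi*area / perimeter^2, and `aspect_ratio` =
#' major / minor.
#'
#' @param nuc a [nucleus()] or a ring matrix.
#' @return named numeric vector of length 10.
#' @export
morphology_features <- function(nuc) {
  m <- if (inherits(nuc, "nucleus")) nuc$polygon else close_ring(as.matrix(nuc))
  a <- polygon_area(m)
  if (a <= 0) stop("degenerate polygon: area is zero")
  p <- polygon_perimeter(m)
  mom <- polygon_moments(m)
  # eigenvalues of the 2x2 covariance [[mu20, mu11], [mu11, mu02]]
  tr <- mom["mu20"] + mom["mu02"]
  det <- mom["mu20"] * mom["mu02"] - mom["mu11"]^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  mo <- open_ring(m)
  hull <- mo[grDevices::chull(mo), , drop = FALSE]
  bbox <- (max(mo[, 1]) - min(mo[, 1])) * (max(mo[, 2]) - min(mo[, 2]))
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  setNames(c(a, p, 2 * sqrt(a / pi), major, minor,
             if (l1 > 0) sqrt(1 - l2 / l1) else 0,
             a / polygon_area(hull), a / bbox, 4 * pi * a / p^2,
             if (minor > 0) major / minor else Inf),
           MORPHOLOGY_NAMES)
}
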