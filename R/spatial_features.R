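# Density, spatial-uniformity and tumor-lymphocyte interaction features in
# the tumor core and periphery, and the assembly of the full 246-feature
# patient phenotype.
#
# "Uniformity" is realized as quadrat statistics: counts on a 200-px grid
# anchored at the ROI bounding box, keeping quadrats with >= 50% ROI
# coverage (estimated on a 5 x 5 point lattice per quadrat). Interaction is
# the per-tumor-cell count of tumor and lymphocyte neighbors within a
# centroid-to-centroid radius of 50 or 100 px.

roi_flag_column <- c(WHOLE_TUMOR = "whole", TUMOR_CORE = "core",
                     TUMOR_PERIPHERY = "periphery")

roi_points <- function(flags, roi_kind, cell_class = NULL) {
  sel <- flags[[roi_flag_column[[roi_kind]]]]
  if (!is.null(cell_class)) {
    cc <- if (cell_class == "lymph") "LYMPHOCYTE" else toupper(cell_class)
    sel <- sel & flags$cell_class == cc
  }
  flags[sel, c("x", "y"), drop = FALSE]
}

#' Quadrat grid of a region of interest
#'
#' @param map a [cellmap()].
#' @param roi_kind `"TUMOR_CORE"` or `"TUMOR_PERIPHERY"`.
#' @param side quadrat side length in px (default 200).
#' @param coverage_min minimum ROI-coverage fraction for a quadrat to enter
#'   statistics (default 0.5).
#' @return list with the kept quadrat centers, their coverage, and a
#'   counting function `count(points)`.
#' @export
quadrat_grid <- function(map, roi_kind, side = 200, coverage_min = 0.5) {
  reg <- get_roi(map, roi_kind)
  ring <- open_ring(reg$polygon)
  x0 <- min(ring[, 1]); x1 <- max(ring[, 1])
  y0 <- min(ring[, 2]); y1 <- max(ring[, 2])
  nx <- max(1L, ceiling((x1 - x0) / side))
  ny <- max(1L, ceiling((y1 - y0) / side))
  # coverage on a 5x5 lattice of sample points per quadrat
  qi <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  off <- (seq_len(5) - 0.5) / 5 * side
  lat <- expand.grid(dx = off, dy = off)
  cov <- vapply(seq_len(nrow(qi)), function(k) {
    px <- x0 + qi$ix[k] * side + lat$dx
    py <- y0 + qi$iy[k] * side + lat$dy
    mean(point_in_region(px, py, reg))
  }, 0)
  keep <- cov >= coverage_min
  list(x0 = x0, y0 = y0, side = side, nx = nx, ny = ny,
       ix = qi$ix[keep], iy = qi$iy[keep], coverage = cov[keep],
       count = function(pts) {
         if (nrow(pts) == 0) return(rep(0L, sum(keep)))
         cx <- pmin(nx - 1L, pmax(0L, floor((pts$x - x0) / side)))
         cy <- pmin(ny - 1L, pmax(0L, floor((pts$y - y0) / side)))
         key <- cx + nx * cy
         kept_key <- qi$ix[keep] + nx * qi$iy[keep]
         as.integer(table(factor(key, levels = kept_key)))
       })
}

#' Morisita aggregation index from quadrat counts
#'
#' Equals 1 in expectation under complete spatial randomness, > 1 for
#' clustered patterns.
#'
#' @param counts integer vector of quadrat counts.
#' @return numeric (NA when fewer than 2 points).
#' @export
morisita_index <- function(counts) {
  n_tot <- sum(counts)
  if (n_tot < 2) return(NA_real_)
  length(counts) * sum(counts * (counts - 1)) / (n_tot * (n_tot - 1))
}

#' Density and spatial-homogeneity features of one cell class in one ROI
#'
#' Seven statistics: density (cells per 10^4 px^2 of ROI area), quadrat
#' count mean, sample sd and coefficient of variation, fraction of empty
#' quadrats, Morisita index, and mean nearest-neighbor distance (px).
#'
#' @param map a [cellmap()].
#' @param roi_kind `"TUMOR_CORE"` or `"TUMOR_PERIPHERY"`.
#' @param cell_class `"tumor"` or `"lymph"`.
#' @param side quadrat side (px).
#' @param flags optional precomputed [assign_roi()] table.
#' @param grid optional precomputed [quadrat_grid()].
#' @return named numeric vector of length 7.
#' @export
density_homogeneity <- function(map, roi_kind, cell_class, side = 200,
                                flags = NULL, grid = NULL) {
  if (is.null(flags)) flags <- assign_roi(map, quiet = TRUE)
  if (is.null(grid)) grid <- quadrat_grid(map, roi_kind, side)
  area <- roi_area(get_roi(map, roi_kind))
  if (area <= 0) stop(roi_kind, ": ROI area is zero")
  pts <- roi_points(flags, roi_kind, cell_class)
  counts <- grid$count(pts)
  mu <- mean(counts)
  sdev <- sd(counts)
  nn <- if (nrow(pts) >= 2) mean_nn_distance_cpp(pts$x, pts$y) else NA_real_
  setNames(c(nrow(pts) / area * 1e4, mu, sdev,
             if (mu > 0) sdev / mu else NA_real_,
             mean(counts == 0), morisita_index(counts), nn),
           DH_STATS)
}

#' Tumor-cell neighbor-count interaction matrix
#'
#' For every tumor nucleus in the ROI, the number of tumor and of
#' lymphocyte nuclei (in the same ROI) whose centroid lies within Euclidean
#' distance <= `radius` of the focal centroid, the focal nucleus excluded.
#' Counts are computed with a uniform-grid spatial index whose arithmetic
#' is identical to the naive all-pairs scan.
#'
#' @param map a [cellmap()].
#' @param roi_kind ROI kind.
#' @param radius neighborhood radius in px (> 0).
#' @param flags optional precomputed [assign_roi()] table.
#' @return object of class `interaction_matrix`: list with `roi_kind`,
#'   `radius`, and `counts` (tumor cells x 2, columns `tumor_neighbors`,
#'   `lymphocyte_neighbors`).
#' @export
interaction_matrix <- function(map, roi_kind, radius, flags = NULL) {
  stopifnot(radius > 0)
  if (is.null(flags)) flags <- assign_roi(map, quiet = TRUE)
  tum <- roi_points(flags, roi_kind, "tumor")
  lym <- roi_points(flags, roi_kind, "lymph")
  counts <- neighbor_counts_cpp(tum$x, tum$y, lym$x, lym$y, radius)
  colnames(counts) <- c("tumor_neighbors", "lymphocyte_neighbors")
  structure(list(roi_kind = roi_kind, radius = radius, counts = counts),
            class = "interaction_matrix")
}

count_stats <- function(v) {
  if (length(v) == 0) return(setNames(rep(NA_real_, 8), INTERACTION_STATS))
  mu <- mean(v)
  sdev <- if (length(v) > 1) sd(v) else 0
  m2 <- mean((v - mu)^2)
  skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
  p <- as.vector(table(v)) / length(v)
  setNames(c(mu, sdev, median(v), max(v), skew,
             quantile(v, 0.75, names = FALSE), mean(v == 0),
             -sum(p * log2(p))),
           INTERACTION_STATS)
}

#' Statistical summary of an interaction matrix
#'
#' Per neighbor class (tumor, lymphocyte): mean, sample sd, median, max,
#' skewness, 75th percentile, fraction of zeros, and Shannon entropy (bits)
#' of the count histogram — 16 statistics.
#'
#' @param M an [interaction_matrix()].
#' @return named numeric vector of length 16; all-missing when the matrix
#'   is empty.
#' @export
interaction_features <- function(M) {
  stopifnot(inherits(M, "interaction_matrix"))
  out <- c(count_stats(M$counts[, "tumor_neighbors"]),
           count_stats(M$counts[, "lymphocyte_neighbors"]))
  names(out) <- paste0("tumor_", rep(c("tumor", "lymph"), each = 8),
                       "_relation_", rep(INTERACTION_STATS, 2))
  out
}

#' Composite count features
#'
#' Lymphocyte:tumor count ratio and total nuclei count in tumor core and
#' periphery (4 features, registry category "composite").
#'
#' @param map a [cellmap()].
#' @param flags optional precomputed [assign_roi()] table.
#' @param quiet suppress the missing-ratio message.
#' @return named numeric vector of length 4.
#' @export
composite_features <- function(map, flags = NULL, quiet = FALSE) {
  if (is.null(flags)) flags <- assign_roi(map, quiet = TRUE)
  out <- numeric(0)
  for (reg in c("TUMOR_CORE", "TUMOR_PERIPHERY")) {
    sel <- flags[[roi_flag_column[[reg]]]]
    nt <- sum(sel & flags$cell_class == "TUMOR")
    nl <- sum(sel & flags$cell_class == "LYMPHOCYTE")
    ratio <- if (nt > 0) nl / nt else NA_real_
    if (nt == 0 && !quiet)
      message(map$specimen_id, ": no tumor cells in ", reg,
              "; ratio is missing")
    out <- c(out, ratio, sum(sel))
  }
  setNames(out, composite_feature_names())
}

#' Extract the full 246-feature phenotype of one specimen
#'
#' Concatenates 150 nuclear features (whole tumor), 28 density/homogeneity
#' features, 64 interaction features and 4 composite features, in registry
#' order. Sub-operation failures propagate as missing values with a
#' message, not as errors.
#'
#' @param map a [cellmap()].
#' @param image RGB array or grayscale matrix for the intensity/texture/
#'   color descriptors.
#' @param quadrat_side quadrat side length in px.
#' @param radii interaction radii in px (default `c(50, 100)`).
#' @param quiet suppress per-specimen messages.
#' @return named numeric vector of length 246.
#' @export
extract_features <- function(map, image, quadrat_side = 200,
                             radii = c(50, 100), quiet = TRUE) {
  stopifnot(length(radii) == 2, all(radii > 0), diff(radii) > 0)
  flags <- assign_roi(map, quiet = quiet)

  nucf <- tryCatch(
    aggregate_patient(nuclei_descriptor_table(map, image, flags),
                      quiet = quiet),
    error = function(e) {
      if (!quiet) message(map$specimen_id, ": nuclear features missing (",
                          conditionMessage(e), ")")
      setNames(rep(NA_real_, 150), nuclei_feature_names())
    })

  dh <- numeric(0)
  for (reg in c("TUMOR_CORE", "TUMOR_PERIPHERY")) {
    grid <- quadrat_grid(map, reg, quadrat_side)
    for (cls in c("tumor", "lymph"))
      dh <- c(dh, density_homogeneity(map, reg, cls, quadrat_side,
                                      flags = flags, grid = grid))
  }
  names(dh) <- dh_feature_names()

  inter <- numeric(0)
  for (reg in c("TUMOR_CORE", "TUMOR_PERIPHERY"))
    for (r in radii)
      inter <- c(inter,
                 interaction_features(interaction_matrix(map, reg, r, flags)))
  names(inter) <- interaction_feature_names()

  comp <- composite_features(map, flags, quiet = quiet)
  c(nucf, dh, inter, comp)
}

#' Extract features for a whole cohort
#'
#' @param maps list of [cellmap()] objects.
#' @param images list of RGB arrays (same order), or a function
#'   `function(map) image` for lazy loading.
#' @param ... passed to [extract_features()].
#' @return matrix (specimens x 246) with specimen ids as rownames.
#' @export
extract_cohort <- function(maps, images, ...) {
  rows <- lapply(seq_along(maps), function(i) {
    img <- if (is.function(images)) images(maps[[i]]) else images[[i]]
    extract_features(maps[[i]], img, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(maps, `[[`, "", "specimen_id")
  out
}
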