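# Per-nucleus intensity, texture and color descriptors, and their
# aggregation to 150 patient-level features.
#
# Descriptors are computed on the pixels whose centers fall inside the
# nucleus polygon. Grayscale is the Rec. 601 luminance
# 0.299 R + 0.587 G + 0.114 B. Within-nucleus moments use the population
# (1/n) denominator; aggregation across nuclei uses the sample (n - 1)
# standard deviation.

#' Convert an RGB image to luminance
#'
#' @param image h x w x 3 array (values 0..255 or 0..1, scaled to 0..255),
#'   an `he_patch`, or an already-gray matrix (returned after scaling).
#' @return h x w matrix, values 0..255.
#' @export
as_gray <- function(image) {
  if (inherits(image, "he_patch"))
    return(t(0.299 * image$R + 0.587 * image$G + 0.114 * image$B))
  image <- scale255(image)
  if (is.matrix(image)) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

scale255 <- function(image) {
  if (max(image) <= 1) image * 255 else image
}

# Normalize any accepted image form to the internal x-major `he_patch`
# layout (channel matrices with nrow = width, m[x+1, y+1] = pixel (x, y)).
image_xy <- function(image) {
  if (inherits(image, "he_patch")) return(image)
  image <- scale255(image)
  if (is.matrix(image)) {
    tm <- t(image)
    structure(list(R = tm, G = tm, B = tm, gray_only = TRUE),
              class = "he_patch")
  } else {
    structure(list(R = t(image[, , 1]), G = t(image[, , 2]),
                   B = t(image[, , 3])), class = "he_patch")
  }
}

# run the compiled descriptor kernel on a set of polygons
descriptor_matrix <- function(polys, image) {
  ch <- image_xy(image)
  gs <- luminance_sobel_cpp(ch$R, ch$G, ch$B)
  out <- nucleus_descriptors_cpp(polys, gs$gray, ch$R, ch$G, ch$B,
                                 gs$sobel, gs$otsu)
  colnames(out) <- c(HISTOGRAM_NAMES, TEXTURE_NAMES, COLOR_NAMES)
  out
}

single_descriptor_row <- function(nuc, image) {
  poly <- if (inherits(nuc, "nucleus")) nuc$polygon else close_ring(as.matrix(nuc))
  descriptor_matrix(list(poly), image)[1, ]
}

#' First-order intensity histogram descriptors of one nucleus
#'
#' Over the grayscale pixels inside the polygon: mean, population sd,
#' skewness, excess kurtosis (both 0 when sd = 0), Shannon entropy in bits
#' over 32 bins spanning \[0, 255\], and the 10th/90th percentiles.
#'
#' @param nuc a [nucleus()] or ring matrix.
#' @param image grayscale matrix or RGB array.
#' @return named numeric vector of length 7.
#' @export
histogram_features <- function(nuc, image) {
  row <- single_descriptor_row(nuc, image)
  out <- row[HISTOGRAM_NAMES]
  if (any(is.na(out))) stop("nucleus mask is empty inside the image")
  out
}

#' Texture descriptors of one nucleus
#'
#' 13 Haralick statistics of the gray-level co-occurrence matrix (32 gray
#' levels, symmetric, normalized, averaged over the 4 directions) at pixel
#' offsets 1 and 2, plus 5 Sobel gradient-magnitude statistics (mean, sd,
#' skewness, 90th percentile, and the fraction of in-mask pixels above the
#' Otsu threshold of the whole patch's gradient magnitude). Masks under 4
#' pixels yield an all-missing row.
#'
#' @inheritParams histogram_features
#' @return named numeric vector of length 31.
#' @export
texture_features <- function(nuc, image) {
  row <- single_descriptor_row(nuc, image)
  if (all(is.na(row))) stop("nucleus mask is empty inside the image")
  row[TEXTURE_NAMES]
}

#' Color descriptors of one nucleus
#'
#' Per RGB channel: mean, population sd, skewness, 32-bin entropy, 10th
#' percentile, median, 90th percentile, min, max (9 x 3 = 27).
#'
#' @param nuc a [nucleus()] or ring matrix.
#' @param image RGB array (h x w x 3) or `he_patch`; grayscale input is an
#'   error — use [histogram_features()] for single-channel statistics.
#' @return named numeric vector of length 27.
#' @export
color_features <- function(nuc, image) {
  if (is.matrix(image) ||
      (inherits(image, "he_patch") && isTRUE(image$gray_only)))
    stop("color_features needs an RGB array; ",
         "use histogram_features() for grayscale input")
  row <- single_descriptor_row(nuc, image)
  if (all(is.na(row))) stop("nucleus mask is empty inside the image")
  row[COLOR_NAMES]
}

#' Per-nucleus descriptor table for tumor nuclei in the whole tumor
#'
#' Computes all 75 base descriptors (10 morphology from the polygon, 7
#' histogram, 31 texture, 27 color from the image) for every tumor nucleus
#' whose centroid lies in the whole-tumor ROI.
#'
#' @param map a [cellmap()].
#' @param image RGB array or grayscale matrix covering the map.
#' @param flags optional precomputed [assign_roi()] table.
#' @return matrix (nuclei x 75) with rownames = nucleus ids.
#' @export
nuclei_descriptor_table <- function(map, image, flags = NULL) {
  if (is.null(flags)) flags <- assign_roi(map, quiet = TRUE)
  keep <- which(flags$cell_class == "TUMOR" & flags$whole)
  nuclei <- map$nuclei[keep]
  polys <- lapply(nuclei, `[[`, "polygon")
  morph <- morphology_batch_cpp(polys)
  desc <- descriptor_matrix(polys, image)
  out <- cbind(morph, desc)
  colnames(out) <- BASE_DESCRIPTORS
  rownames(out) <- flags$nucleus_id[keep]
  out
}

#' Aggregate per-nucleus descriptors to the patient level
#'
#' Mean and sample (n - 1) standard deviation of each of the 75 base
#' descriptors over tumor nuclei; missing descriptor values are excluded
#' pairwise and the affected nucleus count is reported.
#'
#' @param rows matrix from [nuclei_descriptor_table()] (>= 2 rows).
#' @param quiet suppress the missing-row message.
#' @return named numeric vector of length 150
#'   (`tumor_<descriptor>_<mean|sd>`).
#' @export
aggregate_patient <- function(rows, quiet = FALSE) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2)
    stop("need at least 2 tumor nuclei to aggregate (got ", nrow(rows), ")")
  n_missing <- sum(!complete.cases(rows))
  if (n_missing > 0 && !quiet)
    message(n_missing, " nuclei with missing descriptors excluded pairwise")
  mu <- colMeans(rows, na.rm = TRUE)
  sdev <- apply(rows, 2, sd, na.rm = TRUE)
  out <- as.vector(rbind(mu, sdev))
  names(out) <- nuclei_feature_names()
  out
}
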