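# Data model and GeoJSON I/O for typed single-cell maps.
#
# Coordinates are 0-based pixels, x to the right, y down, matching raster
# indexing of the image patches. Polygon rings are stored closed (first
# vertex repeated as the last). Point-in-polygon tests count the boundary
# as inside.

#' Construct a nucleus
#'
#' @param id integer identifier, unique within a specimen.
#' @param polygon numeric matrix with columns x, y; a closed simple ring
#'   (the first vertex may be repeated as the last; if not, it is closed
#'   automatically).
#' @param cell_class one of `"TUMOR"`, `"LYMPHOCYTE"`, `"OTHER"`.
#' @param centroid optional length-2 numeric (x, y); computed from the
#'   polygon (area centroid) when missing.
#' @param check validate the polygon (simplicity, positive area)?
#' @return an object of class `nucleus`.
#' @export
nucleus <- function(id, polygon, cell_class, centroid = NULL, check = TRUE) {
  polygon <- close_ring(as.matrix(polygon))
  if (!cell_class %in% CELL_CLASSES)
    stop("nucleus ", id, ": cell_class must be one of ",
         paste(CELL_CLASSES, collapse = ", "), " (got '", cell_class, "')")
  if (check) {
    if (nrow(polygon) < 4)  # closed ring: >= 3 distinct vertices
      stop("nucleus ", id, ": polygon needs at least 3 vertices")
    if (polygon_area(polygon) <= 0)
      stop("nucleus ", id, ": polygon has non-positive area")
    if (!ring_is_simple(polygon))
      stop("nucleus ", id, ": polygon is self-intersecting")
  }
  if (is.null(centroid)) centroid <- polygon_centroid(polygon)
  structure(list(id = as.integer(id), polygon = polygon,
                 centroid = as.numeric(centroid),
                 cell_class = cell_class),
            class = "nucleus")
}

#' Construct a region of interest
#'
#' The tumor periphery may be an annulus: a band between `polygon` (outer
#' ring) and `inner` (inner ring).
#'
#' @param kind one of `"WHOLE_TUMOR"`, `"TUMOR_CORE"`, `"TUMOR_PERIPHERY"`.
#' @param polygon outer ring (matrix with columns x, y).
#' @param inner optional inner ring for an annulus.
#' @return an object of class `roi`.
#' @export
roi <- function(kind, polygon, inner = NULL) {
  if (!kind %in% ROI_KINDS)
    stop("roi kind must be one of ", paste(ROI_KINDS, collapse = ", "))
  polygon <- close_ring(as.matrix(polygon))
  if (!is.null(inner)) inner <- close_ring(as.matrix(inner))
  structure(list(kind = kind, polygon = polygon, inner = inner),
            class = "roi")
}

#' Construct a single-cell map
#'
#' @param specimen_id nonempty string.
#' @param nuclei list of [nucleus()] objects.
#' @param rois list of [roi()] objects (a valid specimen carries all three
#'   kinds).
#' @param pixel_size_um physical pixel size in micrometers (default 0.25,
#'   40x magnification). All analysis radii remain in pixels.
#' @param image_ref optional path to the RGB patch.
#' @return an object of class `cellmap`.
#' @export
cellmap <- function(specimen_id, nuclei, rois, pixel_size_um = 0.25,
                    image_ref = NULL) {
  if (!is.character(specimen_id) || nchar(specimen_id) == 0)
    stop("specimen_id must be a nonempty string")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(specimen_id = specimen_id, nuclei = nuclei, rois = rois,
                 pixel_size_um = pixel_size_um, image_ref = image_ref),
            class = "cellmap")
}

#' @export
print.cellmap <- function(x, ...) {
  cls <- table(factor(vapply(x$nuclei, `[[`, "", "cell_class"),
                      levels = CELL_CLASSES))
  cat("<cellmap>", x$specimen_id, "\n")
  cat("  nuclei:", length(x$nuclei),
      sprintf("(%d tumor, %d lymphocyte, %d other)",
              cls["TUMOR"], cls["LYMPHOCYTE"], cls["OTHER"]), "\n")
  cat("  rois:", paste(vapply(x$rois, `[[`, "", "kind"), collapse = ", "), "\n")
  cat("  pixel size:", x$pixel_size_um, "um\n")
  invisible(x)
}

close_ring <- function(m) {
  if (nrow(m) >= 2 && !all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

open_ring <- function(m) {
  if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m[-nrow(m), , drop = FALSE]
  else m
}

# segment-intersection simplicity check (open ring, O(n^2); nuclei are small)
ring_is_simple <- function(m) {
  m <- open_ring(m)
  n <- nrow(m)
  if (n < 3) return(FALSE)
  seg <- cbind(m, m[c(2:n, 1), ])  # x1 y1 x2 y2
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (segments_cross(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b) {
  d1 <- cross2(b[3] - b[1], b[4] - b[2], a[1] - b[1], a[2] - b[2])
  d2 <- cross2(b[3] - b[1], b[4] - b[2], a[3] - b[1], a[4] - b[2])
  d3 <- cross2(a[3] - a[1], a[4] - a[2], b[1] - a[1], b[2] - a[2])
  d4 <- cross2(a[3] - a[1], a[4] - a[2], b[3] - a[1], b[4] - a[2])
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx

#' Point-in-region test
#'
#' Tests whether points fall inside an ROI (boundary counts as inside).
#' For an annulus the band between outer and inner ring is inside; points
#' strictly inside the inner ring are outside.
#'
#' @param x,y point coordinates (pixels).
#' @param region an [roi()] object or a ring matrix.
#' @return logical vector.
#' @export
point_in_region <- function(x, y, region) {
  if (inherits(region, "roi")) {
    outer_pos <- ring_position_cpp(x, y, region$polygon[, 1], region$polygon[, 2])
    inside <- outer_pos > 0L
    if (!is.null(region$inner)) {
      inner_pos <- ring_position_cpp(x, y, region$inner[, 1], region$inner[, 2])
      inside <- inside & inner_pos != 2L
    }
    inside
  } else {
    ring_position_cpp(x, y, region[, 1], region[, 2]) > 0L
  }
}

roi_area <- function(region) {
  a <- polygon_area(region$polygon)
  if (!is.null(region$inner)) a <- a - polygon_area(region$inner)
  a
}

get_roi <- function(map, kind) {
  for (r in map$rois) if (r$kind == kind) return(r)
  stop("cellmap '", map$specimen_id, "' has no ", kind, " ROI")
}

#' Assign nuclei to regions of interest
#'
#' Flags each nucleus for membership in each ROI kind by a point-in-polygon
#' test on its centroid (boundary counts as inside). Nuclei outside all
#' ROIs are flagged, never dropped; their count is reported as a message.
#'
#' @param map a [cellmap()].
#' @param quiet suppress the outside-count message.
#' @return data.frame with columns `nucleus_id`, `cell_class`, `x`, `y`,
#'   `whole`, `core`, `periphery` (logical flags).
#' @export
assign_roi <- function(map, quiet = FALSE) {
  kinds <- vapply(map$rois, `[[`, "", "kind")
  if (!all(ROI_KINDS %in% kinds))
    stop("all three ROI kinds must be present; missing: ",
         paste(setdiff(ROI_KINDS, kinds), collapse = ", "))
  cx <- vapply(map$nuclei, function(n) n$centroid[1], 0)
  cy <- vapply(map$nuclei, function(n) n$centroid[2], 0)
  out <- data.frame(
    nucleus_id = vapply(map$nuclei, `[[`, 0L, "id"),
    cell_class = vapply(map$nuclei, `[[`, "", "cell_class"),
    x = cx, y = cy,
    whole = point_in_region(cx, cy, get_roi(map, "WHOLE_TUMOR")),
    core = point_in_region(cx, cy, get_roi(map, "TUMOR_CORE")),
    periphery = point_in_region(cx, cy, get_roi(map, "TUMOR_PERIPHERY")))
  n_out <- sum(!(out$whole | out$core | out$periphery))
  if (n_out > 0 && !quiet)
    message(map$specimen_id, ": ", n_out, " nuclei outside all ROIs")
  out
}

#' Read a single-cell map from GeoJSON
#'
#' Expects an RFC 7946 FeatureCollection in pixel coordinates. Nucleus
#' features carry `properties.id` and `properties.cell_class`; ROI features
#' carry `properties.roi_kind` (a second ring encodes an annulus hole).
#'
#' @param path file path.
#' @param check validate nucleus polygons (simplicity, area)?
#' @return a [cellmap()].
#' @export
read_cellmap <- function(path, check = TRUE) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  props <- gj$properties
  nuclei <- list()
  rois <- list()
  for (f in gj$features) {
    p <- f$properties
    rings <- lapply(f$geometry$coordinates, function(ring)
      do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]]))))
    if (!is.null(p$roi_kind)) {
      rois[[length(rois) + 1L]] <- roi(
        p$roi_kind, rings[[1]],
        inner = if (length(rings) > 1) rings[[2]] else NULL)
    } else {
      if (is.null(p$cell_class))
        stop("feature id ", p$id, ": missing cell_class")
      nuclei[[length(nuclei) + 1L]] <- nucleus(
        p$id, rings[[1]], p$cell_class,
        centroid = if (!is.null(p$centroid)) unlist(p$centroid),
        check = check)
    }
  }
  cellmap(props$specimen_id, nuclei, rois,
          pixel_size_um = props$pixel_size_um %||% 0.25,
          image_ref = props$image_ref)
}

#' Write a single-cell map to GeoJSON
#'
#' Lossless inverse of [read_cellmap()]: one feature per nucleus and per
#' ROI, rings closed, pixel coordinates.
#'
#' @param map a [cellmap()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cellmap <- function(map, path) {
  ring_json <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  feats <- c(
    lapply(map$nuclei, function(n) list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(ring_json(n$polygon))),
      properties = list(id = n$id, cell_class = n$cell_class,
                        centroid = n$centroid))),
    lapply(map$rois, function(r) list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = c(list(ring_json(r$polygon)),
                                      if (!is.null(r$inner)) list(ring_json(r$inner)))),
      properties = list(roi_kind = r$kind))))
  obj <- list(type = "FeatureCollection",
              properties = list(specimen_id = map$specimen_id,
                                pixel_size_um = map$pixel_size_um,
                                crs = "pixel",
                                image_ref = map$image_ref),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with header `specimen_id, os_time, os_event, stage, grade, sex` plus
#' optional extra label columns. `os_time` must be nonnegative and
#' `os_event` in {0, 1}.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  cl <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "os_time", "os_event", "stage", "grade", "sex")
  miss <- setdiff(need, names(cl))
  if (length(miss) > 0)
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (any(cl$os_time < 0)) stop("os_time must be nonnegative")
  if (!all(cl$os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  cl
}

`%||%` <- function(a, b) if (is.null(a)) b else a
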