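# Synthetic H&E-like cohort generator.
#
# Each simulated specimen is a 2000 x 2000 px patch: tumor cells from a
# homogeneous Poisson or Thomas cluster process, lymphocytes from an
# inhomogeneous Poisson process whose intensity is modulated by a Gaussian
# kernel field around tumor cells (alpha > 0 attraction / colocalization,
# alpha < 0 exclusion, clamped at a floor of 0.05), other cells homogeneous
# Poisson. Nuclei are 32-vertex ellipses with log-normal equivalent
# diameters; patches are rendered in an eosin-pink / hematoxylin-purple
# palette with shared Gaussian pixel noise and smooth intra-nuclear
# texture. Survival times are exponential with a subtype-specific hazard
# under independent uniform censoring.
#
# The three default subtype specs plant the qualitative signature the
# analysis is designed to recover: S1 has the lowest tumor density, the
# most homogeneous spatial distribution, the highest lymphocyte density
# and tumor-lymphocyte colocalization, and the best prognosis; S2 and S3
# have dense, spatially clustered tumor cells, sparse lymphocytes and a
# doubled hazard. S2 is immune-excluded (lymphocytes repelled from tumor
# clusters) with tight, compact tumor clusters; S3 grows in loose, broad
# clusters and has the largest tumor nuclei (about 1.3x the S1 median
# equivalent diameter).

#' Default subtype specifications
#'
#' @return named list of three subtype spec lists (`S1`, `S2`, `S3`); see
#'   the package vignette for the meaning and units of every field.
#' @export
default_subtype_specs <- function() {
  list(
    S1 = list(name = "S1",
              tumor = list(type = "poisson", kappa = 1.0),
              lymph0 = 0.12, alpha = 4, bandwidth = 60,
              size_median = 24, size_sigma = 0.15,
              other_kappa = 0.5, hazard = 0.015),
    S2 = list(name = "S2",
              tumor = list(type = "thomas", parent_kappa = 0.03, mu = 75,
                           sigma = 80),
              lymph0 = 0.3, alpha = -2, bandwidth = 60,
              size_median = 28, size_sigma = 0.15,
              other_kappa = 0.5, hazard = 0.03),
    S3 = list(name = "S3",
              tumor = list(type = "thomas", parent_kappa = 0.06, mu = 40,
                           sigma = 150),
              lymph0 = 0.3, alpha = 0, bandwidth = 60,
              size_median = 31, size_sigma = 0.15,
              other_kappa = 0.5, hazard = 0.03))
}

#' Apply per-specimen biological heterogeneity to a subtype spec
#'
#' Tumors of one subtype are not identical: specimen-level multipliers
#' (log-normal, drawn from the current RNG stream) scale the process
#' intensities (sd `intensity_sigma` on the log scale) and the median
#' nuclear size (sd `size_sigma`), keeping the between-subtype orderings
#' while giving each subtype a realistic continuous spread.
#'
#' @param spec a subtype spec.
#' @param intensity_sigma log-sd of the intensity multiplier (default
#'   0.2).
#' @param size_sigma log-sd of the size multiplier (default 0.03).
#' @return the jittered spec.
#' @export
jitter_spec <- function(spec, intensity_sigma = 0.2, size_sigma = 0.03) {
  m_tum <- exp(rnorm(1, 0, intensity_sigma))
  m_lym <- exp(rnorm(1, 0, intensity_sigma))
  if (spec$tumor$type == "poisson")
    spec$tumor$kappa <- spec$tumor$kappa * m_tum
  else
    spec$tumor$parent_kappa <- spec$tumor$parent_kappa * m_tum
  spec$lymph0 <- spec$lymph0 * m_lym
  spec$size_median <- spec$size_median * exp(rnorm(1, 0, size_sigma))
  spec
}

#' Rectangular ROI surrogate geometry
#'
#' Whole tumor = the full patch rectangle; tumor core = the rectangle
#' eroded by `core_margin`; tumor periphery = the outer band of width
#' `band_width` (an annulus). Core and periphery are disjoint by
#' construction when `core_margin > band_width`.
#'
#' @param width,height patch size in px.
#' @param core_margin erosion margin for the core (default 300 px).
#' @param band_width periphery band width (default 200 px).
#' @return list of three [roi()] objects.
#' @export
synthetic_rois <- function(width, height, core_margin = 300,
                           band_width = 200) {
  stopifnot(core_margin > band_width, 2 * core_margin < width,
            2 * core_margin < height)
  rect <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
  list(
    roi("WHOLE_TUMOR", rect(0, 0, width, height)),
    roi("TUMOR_CORE", rect(core_margin, core_margin,
                           width - core_margin, height - core_margin)),
    roi("TUMOR_PERIPHERY", rect(0, 0, width, height),
        inner = rect(band_width, band_width,
                     width - band_width, height - band_width)))
}

#' Simulate a typed point pattern for one specimen
#'
#' Positions and classes only; nuclei shapes are attached by
#' [attach_nuclei()]. Reproducible from the RNG state (set a seed before
#' calling, or pass one).
#'
#' @param spec a subtype spec (see [default_subtype_specs()]).
#' @param width,height patch size in px.
#' @param seed optional integer seed.
#' @return data.frame with columns `x`, `y`, `class`.
#' @export
simulate_pointpattern <- function(spec, width = 2000, height = 2000,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  area_u <- width * height / 1e4  # area in units of 10^4 px^2

  expected <- (if (spec$tumor$type == "poisson") spec$tumor$kappa
               else spec$tumor$parent_kappa * spec$tumor$mu) * area_u +
    spec$lymph0 * area_u * (1 + max(0, spec$alpha)) + spec$other_kappa * area_u
  if (expected > 1e5)
    stop("expected cell count ", round(expected), " exceeds 1e5; ",
         "refusing to simulate")

  # tumor cells
  if (spec$tumor$type == "poisson") {
    n <- rpois(1, spec$tumor$kappa * area_u)
    tum <- cbind(runif(n, 0, width), runif(n, 0, height))
  } else if (spec$tumor$type == "thomas") {
    npar <- rpois(1, spec$tumor$parent_kappa * area_u)
    noff <- rpois(npar, spec$tumor$mu)
    px <- runif(npar, 0, width); py <- runif(npar, 0, height)
    tum <- cbind(rnorm(sum(noff), rep(px, noff), spec$tumor$sigma),
                 rnorm(sum(noff), rep(py, noff), spec$tumor$sigma))
    keep <- tum[, 1] >= 0 & tum[, 1] <= width &
            tum[, 2] >= 0 & tum[, 2] <= height
    tum <- tum[keep, , drop = FALSE]
  } else stop("unknown tumor process type: ", spec$tumor$type)

  # lymphocytes: inhomogeneous Poisson via thinning;
  # lambda(x) = lymph0 * max(0.05, 1 + alpha * sum_i G(x - t_i; bandwidth))
  if (spec$alpha == 0 || nrow(tum) == 0) {
    n <- rpois(1, spec$lymph0 * area_u)
    lym <- cbind(runif(n, 0, width), runif(n, 0, height))
  } else {
    ftum <- gauss_field_cpp(tum[, 1], tum[, 2], tum[, 1], tum[, 2],
                            spec$bandwidth)
    relmax <- max(0.05, 1 + spec$alpha * max(ftum)) * 1.3
    nprop <- rpois(1, spec$lymph0 * area_u * relmax)
    qx <- runif(nprop, 0, width); qy <- runif(nprop, 0, height)
    f <- gauss_field_cpp(qx, qy, tum[, 1], tum[, 2], spec$bandwidth)
    rel <- pmax(0.05, 1 + spec$alpha * f)
    keep <- runif(nprop) < rel / relmax
    lym <- cbind(qx[keep], qy[keep])
  }

  n <- rpois(1, spec$other_kappa * area_u)
  oth <- cbind(runif(n, 0, width), runif(n, 0, height))

  data.frame(x = c(tum[, 1], lym[, 1], oth[, 1]),
             y = c(tum[, 2], lym[, 2], oth[, 2]),
             class = rep(c("TUMOR", "LYMPHOCYTE", "OTHER"),
                         c(nrow(tum), nrow(lym), nrow(oth))))
}

# fixed nuclear geometry for the two non-tumor classes
LYMPH_SIZE <- list(median = 12, sigma = 0.10, ecc_max = 0.4)
OTHER_SIZE <- list(median = 16, sigma = 0.15, ecc_max = 0.8)

ellipse_polygon <- function(cx, cy, ed, ecc, theta, nv = 32) {
  # semi-axes with pi*a*b = pi*(ed/2)^2 and b/a = sqrt(1 - ecc^2)
  q <- (1 - ecc^2)^0.25
  a <- (ed / 2) / q
  b <- (ed / 2) * q
  t <- 2 * pi * (seq_len(nv) - 1) / nv
  xs <- a * cos(t); ys <- b * sin(t)
  cbind(cx + xs * cos(theta) - ys * sin(theta),
        cy + xs * sin(theta) + ys * cos(theta))
}

#' Attach elliptical nucleus polygons to a point pattern
#'
#' Tumor nuclei draw their equivalent diameter from the subtype's
#' log-normal size law; lymphocytes and other cells use fixed class-level
#' size laws (small round lymphocytes, intermediate other cells).
#' Eccentricity is uniform on \[0, ecc_max\], orientation uniform.
#' Overlapping nuclei are allowed.
#'
#' @param pts data.frame from [simulate_pointpattern()].
#' @param spec subtype spec (for the tumor size law).
#' @param specimen_id id for the resulting map.
#' @param width,height patch size (for the ROI surrogate).
#' @param core_margin,band_width ROI surrogate geometry (px); see
#'   [synthetic_rois()].
#' @param seed optional integer seed.
#' @return a [cellmap()] with ROIs from [synthetic_rois()].
#' @export
attach_nuclei <- function(pts, spec, specimen_id = "synthetic",
                          width = 2000, height = 2000, core_margin = 300,
                          band_width = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pts)
  ed <- numeric(n); eccmax <- numeric(n)
  for (cc in list(c("TUMOR", spec$size_median, spec$size_sigma, 0.8),
                  c("LYMPHOCYTE", LYMPH_SIZE$median, LYMPH_SIZE$sigma,
                    LYMPH_SIZE$ecc_max),
                  c("OTHER", OTHER_SIZE$median, OTHER_SIZE$sigma,
                    OTHER_SIZE$ecc_max))) {
    sel <- pts$class == cc[1]
    ed[sel] <- exp(rnorm(sum(sel), log(as.numeric(cc[2])),
                         as.numeric(cc[3])))
    eccmax[sel] <- as.numeric(cc[4])
  }
  ecc <- runif(n, 0, eccmax)
  theta <- runif(n, 0, 2 * pi)
  nuclei <- lapply(seq_len(n), function(i)
    nucleus(i, ellipse_polygon(pts$x[i], pts$y[i], ed[i], ecc[i], theta[i]),
            pts$class[i], centroid = c(pts$x[i], pts$y[i]), check = FALSE))
  cellmap(specimen_id, nuclei,
          synthetic_rois(width, height, core_margin, band_width))
}

# H&E-like palette (RGB 0..255)
HE_PALETTE <- list(background = c(230, 180, 200),
                   tumor = c(90, 60, 140),
                   lymphocyte = c(50, 40, 110),
                   other = c(150, 110, 160))

#' Render a cell map to an H&E-like RGB patch
#'
#' Eosin-pink background, hematoxylin-purple tumor nuclei, dark compact
#' lymphocytes; one Gaussian noise field of sd `noise_sd` shared by all
#' channels plus smooth (4-px grid, bilinear) intra-nuclear texture noise.
#'
#' @param map a [cellmap()] with polygons.
#' @param width,height patch size in px (at most 4096 each).
#' @param noise_sd pixel noise sd (default 8; 0 disables).
#' @param texture_sd intra-nuclear texture noise sd (default 12).
#' @param seed optional integer seed.
#' @return object of class `he_patch`: list of matrices `R`, `G`, `B`
#'   (values 0..255).
#' @export
render_patch <- function(map, width = 2000, height = 2000, noise_sd = 8,
                         texture_sd = 12, seed = NULL) {
  if (width > 4096 || height > 4096)
    stop("patch larger than 4096 x 4096 px; refusing to render")
  if (!is.null(seed)) set.seed(seed)
  cls <- match(vapply(map$nuclei, `[[`, "", "cell_class"), CELL_CLASSES)
  # z-order: other cells, then lymphocytes, then tumor nuclei on top, so
  # a tumor nucleus mask reads its own stain even where cells overlap
  ord <- order(match(cls, c(3L, 2L, 1L)))
  colors <- rbind(HE_PALETTE$tumor, HE_PALETTE$lymphocyte, HE_PALETTE$other)
  out <- render_patch_cpp(width, height,
                          lapply(map$nuclei[ord], `[[`, "polygon"),
                          cls[ord], colors, HE_PALETTE$background,
                          noise_sd, texture_sd)
  structure(out, class = "he_patch")
}

#' Write / read an H&E patch as PNG
#' @param patch an `he_patch` (or h x w x 3 array, 0..255).
#' @param path PNG path.
#' @return `path` invisibly; `read_patch` returns an `he_patch`.
#' @export
write_patch <- function(patch, path) {
  arr <- if (inherits(patch, "he_patch"))
    simplify2array(list(t(patch$R), t(patch$G), t(patch$B))) else patch
  png::writePNG(arr / 255, path)
  invisible(path)
}

#' @rdname write_patch
#' @export
read_patch <- function(path) {
  arr <- png::readPNG(path) * 255
  structure(list(R = t(arr[, , 1]), G = t(arr[, , 2]), B = t(arr[, , 3])),
            class = "he_patch")
}

#' Simulate a full synthetic cohort
#'
#' Per patient: point pattern, elliptical nuclei, optional rendered patch,
#' and a clinical record with exponential survival (subtype hazard) under
#' independent uniform censoring on \[0, 120\] months. All randomness
#' derives from `seed` via per-patient sub-seeds recorded in the manifest;
#' the same seed reproduces the cohort exactly.
#'
#' @param n_per_subtype integer vector, patients per subtype (default
#'   20, 20, 20).
#' @param specs subtype specs (default [default_subtype_specs()]).
#' @param patch_size patch side in px (default 2000).
#' @param seed master seed.
#' @param render make image patches available (needed for nuclear
#'   intensity / texture / color features)?
#' @param keep_images hold all rendered patches in memory? The default
#'   (FALSE) stores none: `image_of` re-renders any specimen on demand by
#'   replaying its recorded RNG state, byte-identically, which keeps a
#'   60-specimen cohort small.
#' @param noise_sd render noise sd.
#' @param core_margin,band_width ROI surrogate geometry (px).
#' @return list with `maps`, `images` (NULL unless `keep_images`),
#'   `image_of` (lazy deterministic renderer), `clinical` (data.frame),
#'   `truth` (data.frame with planted subtype), and `manifest`.
#' @export
simulate_cohort <- function(n_per_subtype = c(20, 20, 20),
                            specs = default_subtype_specs(),
                            patch_size = 2000, seed = 1, render = TRUE,
                            keep_images = FALSE, noise_sd = 8,
                            core_margin = 300, band_width = 200) {
  stopifnot(length(n_per_subtype) == length(specs), all(n_per_subtype >= 2))
  set.seed(seed)
  total <- sum(n_per_subtype)
  subseeds <- sample.int(.Machine$integer.max - 1, total)
  subtype_of <- rep(seq_along(specs), n_per_subtype)
  ids <- unlist(lapply(seq_along(specs), function(s)
    sprintf("%s_%02d", specs[[s]]$name, seq_len(n_per_subtype[s]))))

  maps <- vector("list", total)
  images <- if (render && keep_images) vector("list", total) else NULL
  render_states <- vector("list", total)
  clin <- vector("list", total)
  for (i in seq_len(total)) {
    set.seed(subseeds[i])
    spec <- jitter_spec(specs[[subtype_of[i]]])
    os_true <- rexp(1, spec$hazard)
    cens <- runif(1, 0, 120)
    sex <- sample(c("female", "male"), 1, prob = c(0.34, 0.66))
    stage <- sample(paste0("pT", 1:4), 1, prob = c(0.47, 0.27, 0.22, 0.04))
    grade <- sample(paste0("G", 1:4), 1, prob = c(0.14, 0.47, 0.35, 0.04))
    pts <- simulate_pointpattern(spec, patch_size, patch_size)
    maps[[i]] <- attach_nuclei(pts, spec, specimen_id = ids[i],
                               width = patch_size, height = patch_size,
                               core_margin = core_margin,
                               band_width = band_width)
    if (render) {
      render_states[[i]] <- get(".Random.seed", envir = .GlobalEnv)
      if (keep_images)
        images[[i]] <- render_patch(maps[[i]], patch_size, patch_size,
                                    noise_sd = noise_sd)
    }
    clin[[i]] <- data.frame(specimen_id = ids[i],
                            os_time = min(os_true, cens),
                            os_event = as.integer(os_true <= cens),
                            stage = stage, grade = grade, sex = sex)
  }
  image_of <- if (render) {
    function(map) {
      i <- match(map$specimen_id, ids)
      assign(".Random.seed", render_states[[i]], envir = .GlobalEnv)
      render_patch(map, patch_size, patch_size, noise_sd = noise_sd)
    }
  } else NULL
  list(maps = maps, images = images, image_of = image_of,
       clinical = do.call(rbind, clin),
       truth = data.frame(specimen_id = ids,
                          subtype = vapply(specs, `[[`, "", "name")[subtype_of]),
       manifest = list(seed = seed, subseeds = subseeds,
                       n_per_subtype = n_per_subtype,
                       patch_size = patch_size, noise_sd = noise_sd,
                       subtypes = vapply(specs, `[[`, "", "name")))
}

#' Write / read a cohort directory
#'
#' Layout: `cohort/<specimen_id>/cells.geojson` (+ `patch.png` when
#' rendered), `clinical.csv`, `truth.csv`, `manifest.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory.
#' @return `dir` invisibly; `read_cohort` returns a cohort list (images
#'   are loaded lazily via the `image_of` function element).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$maps)) {
    id <- cohort$maps[[i]]$specimen_id
    sub <- file.path(dir, id)
    dir.create(sub, showWarnings = FALSE)
    write_cellmap(cohort$maps[[i]], file.path(sub, "cells.geojson"))
    img <- if (!is.null(cohort$images)) cohort$images[[i]]
           else if (!is.null(cohort$image_of)) cohort$image_of(cohort$maps[[i]])
    if (!is.null(img)) write_patch(img, file.path(sub, "patch.png"))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clinical <- if (file.exists(file.path(dir, "clinical.csv")))
    read_clinical(file.path(dir, "clinical.csv")) else NULL
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  ids <- if (!is.null(clinical)) clinical$specimen_id
         else basename(Filter(function(d) file.exists(file.path(d, "cells.geojson")),
                              list.dirs(dir, recursive = FALSE)))
  maps <- lapply(ids, function(id)
    read_cellmap(file.path(dir, id, "cells.geojson"), check = FALSE))
  manifest_path <- file.path(dir, "manifest.json")
  list(maps = maps, images = NULL,
       image_of = function(map)
         read_patch(file.path(dir, map$specimen_id, "patch.png")),
       clinical = clinical, truth = truth,
       manifest = if (file.exists(manifest_path))
         jsonlite::fromJSON(manifest_path) else NULL)
}
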