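# Shared fixtures and independent oracles, built in code.

# axis-aligned square ring (closed)
square_ring <- function(cx, cy, side) {
  h <- side / 2
  cbind(c(cx - h, cx + h, cx + h, cx - h, cx - h),
        c(cy - h, cy - h, cy + h, cy + h, cy - h))
}

rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
}

# regular ngon approximating a circle
circle_ring <- function(cx, cy, r, nv = 64) {
  t <- 2 * pi * (seq_len(nv) - 1) / nv
  cbind(cx + r * cos(t), cy + r * sin(t))
}

# a small hand-built cell map: rectangle ROI geometry, point-like nuclei
# at given coordinates; core_margin = 0 makes the core cover the patch
toy_cellmap <- function(tumor_xy, lymph_xy = NULL, other_xy = NULL,
                        width = 1000, height = 1000, core_margin = 100,
                        band_width = 50, nucleus_side = 4,
                        id = "toy") {
  pts <- rbind(
    if (!is.null(tumor_xy)) cbind(tumor_xy, 1),
    if (!is.null(lymph_xy)) cbind(lymph_xy, 2),
    if (!is.null(other_xy)) cbind(other_xy, 3))
  nuclei <- lapply(seq_len(nrow(pts)), function(i)
    nucleus(i, square_ring(pts[i, 1], pts[i, 2], nucleus_side),
            CELL_CLASSES_T[pts[i, 3]],
            centroid = pts[i, 1:2], check = FALSE))
  m <- core_margin
  b <- band_width
  rois <- list(
    roi("WHOLE_TUMOR", rect_ring(0, 0, width, height)),
    roi("TUMOR_CORE", rect_ring(m, m, width - m, height - m)),
    roi("TUMOR_PERIPHERY", rect_ring(0, 0, width, height),
        inner = rect_ring(b, b, width - b, height - b)))
  cellmap(id, nuclei, rois)
}
CELL_CLASSES_T <- c("TUMOR", "LYMPHOCYTE", "OTHER")

# independent all-pairs oracle for the interaction matrix (squared-distance
# comparison, mirroring the documented arithmetic)
naive_neighbor_counts <- function(tx, ty, lx, ly, r) {
  nt <- length(tx)
  out <- matrix(0L, nt, 2)
  r2 <- r * r
  for (i in seq_len(nt)) {
    dt <- (tx - tx[i])^2 + (ty - ty[i])^2
    out[i, 1] <- sum(dt <= r2) - 1L
    if (length(lx) > 0) {
      dl <- (lx - tx[i])^2 + (ly - ty[i])^2
      out[i, 2] <- sum(dl <= r2)
    }
  }
  out
}

# exhaustive k-medoids objective (oracle for PAM)
brute_force_pam_objective <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (sel in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(d[sel, , drop = FALSE], 2, min))
    if (obj < best) best <- obj
  }
  best
}

# three well-separated Gaussian blob cohorts for clustering / IGP tests;
# pass `centers` to draw a second cohort around the same cluster centers
make_blob_cohort <- function(n_per, p = 25, sep = 10, sd = 0.5, seed = 1,
                             centers = NULL) {
  set.seed(seed)
  if (is.null(centers)) centers <- matrix(rnorm(3 * p), 3, p) * sep
  X <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(n_per * p, mean = rep(centers[g, ], each = n_per), sd = sd),
           n_per, p)))
  rownames(X) <- paste0("v", seq_len(3 * n_per))
  list(X = X, labels = rep(1:3, each = n_per), centers = centers)
}

# constant-value test image (standard h x w orientation)
constant_image <- function(h, w, value) matrix(value, h, w)

# small RGB array image
rgb_image <- function(r, g, b) {
  simplify2array(list(r, g, b))
}
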