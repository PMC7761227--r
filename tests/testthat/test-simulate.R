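# Synthetic cohort generator: point processes, nuclei, rendering, and
# cohort-level reproducibility.

test_that("poisson tumor counts stay within their sampling bounds", {
  spec <- list(name = "T", tumor = list(type = "poisson", kappa = 5),
               lymph0 = 0, alpha = 0, bandwidth = 60,
               size_median = 20, size_sigma = 0.1, other_kappa = 0,
               hazard = 0.02)
  # kappa * area = 5 * 100 = 500 expected tumor cells
  counts <- vapply(1:40, function(s) {
    pts <- simulate_pointpattern(spec, 1000, 1000, seed = 1000 + s)
    sum(pts$class == "TUMOR")
  }, 0)
  expect_gte(mean(counts >= 440 & counts <= 560), 0.9)
})

test_that("alpha = 0 reduces lymphocytes to a homogeneous Poisson process", {
  spec <- list(name = "T", tumor = list(type = "poisson", kappa = 1),
               lymph0 = 3, alpha = 0, bandwidth = 60,
               size_median = 20, size_sigma = 0.1, other_kappa = 0,
               hazard = 0.02)
  set.seed(91)
  morisita <- vapply(1:40, function(s) {
    pts <- simulate_pointpattern(spec, 1000, 1000)
    lym <- pts[pts$class == "LYMPHOCYTE", ]
    q <- floor(lym$x / 200) + 5 * floor(lym$y / 200)
    counts <- as.integer(table(factor(q, levels = 0:24)))
    morisita_index(counts)
  }, 0)
  # CSR expectation 1; the mean over 40 patterns should be close
  expect_lt(abs(mean(morisita) - 1), 0.05)
})

test_that("colocalization raises lymphocyte counts near tumor cells", {
  base <- list(name = "co",
               tumor = list(type = "thomas", parent_kappa = 0.08, mu = 40,
                            sigma = 60),
               lymph0 = 0.5, alpha = 6, bandwidth = 60,
               size_median = 20, size_sigma = 0.1, other_kappa = 0,
               hazard = 0.02)
  indep <- base
  indep$alpha <- 0
  diffs <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    co <- simulate_pointpattern(base, 1000, 1000)
    set.seed(3000 + s)
    un <- simulate_pointpattern(indep, 1000, 1000)
    mean_l <- function(pts) {
      tum <- pts[pts$class == "TUMOR", ]
      lym <- pts[pts$class == "LYMPHOCYTE", ]
      m <- hespat:::neighbor_counts_cpp(tum$x, tum$y, lym$x, lym$y, 50)
      # per-tumor-cell lymphocyte rate, normalized by realized abundance
      mean(m[, 2]) / max(1, nrow(lym))
    }
    mean_l(co) - mean_l(un)
  }, 0)
  # one-sided test across replicate map pairs
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.01)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("exclusion lowers lymphocyte counts near tumor cells", {
  base <- default_subtype_specs()$S2
  indep <- base
  indep$alpha <- 0
  set.seed(95)
  co <- simulate_pointpattern(base, 1500, 1500)
  un <- simulate_pointpattern(indep, 1500, 1500)
  rate <- function(pts) {
    tum <- pts[pts$class == "TUMOR", ]
    lym <- pts[pts$class == "LYMPHOCYTE", ]
    m <- hespat:::neighbor_counts_cpp(tum$x, tum$y, lym$x, lym$y, 100)
    mean(m[, 2]) / max(1, nrow(lym))
  }
  expect_lt(rate(co), rate(un))
})

test_that("attach_nuclei plants the requested size law", {
  spec <- default_subtype_specs()$S1
  spec$size_sigma <- 0  # degenerate law: all diameters at the median
  pts <- data.frame(x = runif(50, 100, 900), y = runif(50, 100, 900),
                    class = "TUMOR")
  map <- attach_nuclei(pts, spec, width = 1000, height = 1000, seed = 97)
  eds <- vapply(map$nuclei, function(n)
    morphology_features(n)[["equivalent_diameter"]], 0)
  # a 32-gon underestimates the continuous ellipse slightly
  expect_true(all(abs(eds - spec$size_median) / spec$size_median < 0.02))
  expect_lt(sd(eds) / mean(eds), 1e-9)
})

test_that("planted S3 vs S1 nuclear size separates specimens (AUC > 0.9)", {
  specs <- default_subtype_specs()
  mean_ed <- function(spec, s) {
    set.seed(s)
    spec <- jitter_spec(spec)
    pts <- simulate_pointpattern(spec, 1000, 1000)
    map <- attach_nuclei(pts, spec, width = 1000, height = 1000)
    polys <- lapply(map$nuclei[pts$class == "TUMOR"], `[[`, "polygon")
    mean(hespat:::morphology_batch_cpp(polys)[, 3])
  }
  s1 <- vapply(1:10, function(s) mean_ed(specs$S1, 500 + s), 0)
  s3 <- vapply(1:10, function(s) mean_ed(specs$S3, 600 + s), 0)
  auc <- mean(outer(s3, s1, ">"))
  expect_gt(auc, 0.9)
})

test_that("rendering honors the palette and noise contract", {
  spec <- default_subtype_specs()$S1
  pts <- data.frame(x = c(100, 200), y = c(100, 200), class = "TUMOR")
  map <- attach_nuclei(pts, spec, width = 300, height = 300,
                       core_margin = 90, band_width = 60, seed = 99)

  # no nuclei, no noise: constant eosin background
  empty <- cellmap("bg", list(), synthetic_rois(300, 300, 90, 60))
  img0 <- render_patch(empty, 300, 300, noise_sd = 0, texture_sd = 0)
  expect_equal(unique(as.vector(img0$R)), 230)
  expect_equal(unique(as.vector(img0$G)), 180)
  expect_equal(unique(as.vector(img0$B)), 200)

  img <- render_patch(map, 300, 300, seed = 101)
  gray <- 0.299 * img$R + 0.587 * img$G + 0.114 * img$B
  mask <- matrix(FALSE, 300, 300)
  pix <- hespat:::polygon_pixels_cpp(map$nuclei[[1]]$polygon[, 1],
                                     map$nuclei[[1]]$polygon[, 2], 300, 300)
  mask[pix + 1L] <- TRUE
  expect_lt(mean(gray[mask]), mean(gray[!mask]))

  expect_error(render_patch(map, 5000, 5000), "4096")
})

test_that("hematoxylin-purple nuclei are relatively bluer than background", {
  spec <- default_subtype_specs()$S1
  pts <- data.frame(x = 150, y = 150, class = "TUMOR")
  map <- attach_nuclei(pts, spec, width = 300, height = 300,
                       core_margin = 90, band_width = 60, seed = 102)
  img <- render_patch(map, 300, 300, seed = 102)
  pix <- hespat:::polygon_pixels_cpp(map$nuclei[[1]]$polygon[, 1],
                                     map$nuclei[[1]]$polygon[, 2], 300, 300)
  mask <- matrix(FALSE, 300, 300)
  mask[pix + 1L] <- TRUE
  blue_frac <- img$B / (img$R + img$G + img$B)
  expect_gt(mean(blue_frac[mask]), mean(blue_frac[!mask]))
})

test_that("rendered constant-color nuclei have zero histogram spread", {
  spec <- default_subtype_specs()$S1
  pts <- data.frame(x = 150, y = 150, class = "TUMOR")
  map <- attach_nuclei(pts, spec, width = 300, height = 300,
                       core_margin = 90, band_width = 60, seed = 103)
  img <- render_patch(map, 300, 300, noise_sd = 0, texture_sd = 0)
  f <- histogram_features(map$nuclei[[1]], img)
  expect_equal(f[["hist_sd"]], 0)
})

test_that("the desk-scale guard refuses runaway intensities", {
  spec <- default_subtype_specs()$S1
  spec$tumor$kappa <- 1e4
  expect_error(simulate_pointpattern(spec, 2000, 2000), "1e5|exceeds")
})

test_that("cohorts are byte-identical when regenerated from the seed", {
  a <- simulate_cohort(n_per_subtype = c(2, 2, 2), patch_size = 500,
                       core_margin = 125, band_width = 80, seed = 42)
  b <- simulate_cohort(n_per_subtype = c(2, 2, 2), patch_size = 500,
                       core_margin = 125, band_width = 80, seed = 42)
  expect_equal(a$clinical, b$clinical)
  expect_equal(a$truth, b$truth)
  for (i in seq_along(a$maps))
    expect_equal(a$maps[[i]], b$maps[[i]])
  img_a <- a$image_of(a$maps[[3]])
  img_b <- b$image_of(b$maps[[3]])
  expect_identical(img_a, img_b)
  # and the lazy render is itself repeatable
  expect_identical(img_a, a$image_of(a$maps[[3]]))
})

test_that("survival times follow the planted hazard ordering", {
  co <- simulate_cohort(n_per_subtype = c(60, 60, 60), patch_size = 300,
                        core_margin = 90, band_width = 60,
                        seed = 47, render = FALSE)
  cl <- merge(co$clinical, co$truth)
  # uncensored mean survival: S1 (hazard 0.015) should outlive S2/S3 (0.03)
  m <- tapply(cl$os_time, cl$subtype, mean)
  expect_gt(m[["S1"]], m[["S2"]])
  expect_gt(m[["S1"]], m[["S3"]])
})

test_that("cohort directories round-trip through write/read", {
  co <- simulate_cohort(n_per_subtype = c(2, 2, 2), patch_size = 400,
                        core_margin = 100, band_width = 60, seed = 49)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$clinical$specimen_id, co$clinical$specimen_id)
  expect_equal(back$clinical$os_time, co$clinical$os_time)
  expect_equal(back$truth$subtype, co$truth$subtype)
  expect_length(back$maps, 6)
  expect_equal(back$maps[[1]]$nuclei[[5]]$polygon,
               co$maps[[1]]$nuclei[[5]]$polygon)
  img <- back$image_of(back$maps[[1]])
  ref <- co$image_of(co$maps[[1]])
  # PNG quantizes to 8 bits; agreement to within rounding
  expect_lt(max(abs(img$R - ref$R)), 0.51)
})
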