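# Density/homogeneity quadrat statistics, interaction matrix and the
# 246-feature assembly.

test_that("density is cells per 10^4 px^2 of ROI area", {
  grid_xy <- as.matrix(expand.grid(x = seq(50, 950, 100),
                                   y = seq(50, 950, 100)))
  map <- toy_cellmap(tumor_xy = grid_xy, width = 1000, height = 1000,
                     core_margin = 0, band_width = 50)
  # core == whole rectangle (margin 0): area 10^6 px^2, 100 cells
  f <- density_homogeneity(map, "TUMOR_CORE", "tumor")
  expect_equal(f[["density"]], 1.0)
  expect_equal(f[["quadrat_frac_empty"]], 0)
})

test_that("a single occupied quadrat maximizes aggregation statistics", {
  set.seed(2)
  pts <- cbind(runif(25, 10, 150), runif(25, 10, 150))  # inside quadrat 1
  map <- toy_cellmap(tumor_xy = pts, width = 1000, height = 1000,
                     core_margin = 0, band_width = 50)
  f <- density_homogeneity(map, "TUMOR_CORE", "tumor")
  expect_equal(f[["quadrat_frac_empty"]], 24 / 25)
  expect_equal(f[["morisita"]], 25)  # Q * n(n-1) / (N(N-1)) with all in one
  expect_equal(f[["quadrat_mean"]], 1)
  expect_equal(f[["quadrat_cv"]], 5)  # sd of (25, 0 x24) / mean 1
})

test_that("interaction counts follow the stated radii", {
  map <- toy_cellmap(tumor_xy = rbind(c(500, 500)),
                     lymph_xy = rbind(c(530, 500), c(560, 500), c(620, 500)),
                     width = 1000, height = 1000,
                     core_margin = 100, band_width = 50)
  m50 <- interaction_matrix(map, "TUMOR_CORE", 50)
  m100 <- interaction_matrix(map, "TUMOR_CORE", 100)
  expect_equal(m50$counts[1, "lymphocyte_neighbors"], 1,
               ignore_attr = TRUE)
  expect_equal(m100$counts[1, "lymphocyte_neighbors"], 2,
               ignore_attr = TRUE)
  expect_equal(m50$counts[1, "tumor_neighbors"], 0, ignore_attr = TRUE)
})

test_that("tumor-tumor counts are symmetric and exclude the focal cell", {
  map <- toy_cellmap(tumor_xy = rbind(c(400, 400), c(470, 400)),
                     width = 1000, height = 1000)
  m50 <- interaction_matrix(map, "TUMOR_CORE", 50)$counts
  m100 <- interaction_matrix(map, "TUMOR_CORE", 100)$counts
  expect_equal(unname(m50[, "tumor_neighbors"]), c(0L, 0L))
  expect_equal(unname(m100[, "tumor_neighbors"]), c(1L, 1L))
})

test_that("grid-indexed counts equal the naive all-pairs oracle", {
  set.seed(13)
  for (rep in 1:10) {
    nt <- sample(50:400, 1)
    nl <- sample(0:300, 1)
    tx <- runif(nt, 0, 1500); ty <- runif(nt, 0, 1500)
    lx <- runif(nl, 0, 1500); ly <- runif(nl, 0, 1500)
    r <- sample(c(50, 100), 1)
    fast <- hespat:::neighbor_counts_cpp(tx, ty, lx, ly, r)
    slow <- naive_neighbor_counts(tx, ty, lx, ly, r)
    expect_identical(unname(fast), unname(slow))
  }
})

test_that("neighbor counts are monotone in the radius", {
  set.seed(14)
  tx <- runif(300, 0, 800); ty <- runif(300, 0, 800)
  lx <- runif(200, 0, 800); ly <- runif(200, 0, 800)
  c50 <- hespat:::neighbor_counts_cpp(tx, ty, lx, ly, 50)
  c100 <- hespat:::neighbor_counts_cpp(tx, ty, lx, ly, 100)
  expect_true(all(c100 >= c50))
})

test_that("interaction summary statistics match closed forms", {
  m <- structure(list(roi_kind = "TUMOR_CORE", radius = 50,
                      counts = cbind(tumor_neighbors = c(1L, 2L, 3L, 4L),
                                     lymphocyte_neighbors = c(3L, 3L, 3L, 3L))),
                 class = "interaction_matrix")
  f <- interaction_features(m)
  expect_equal(f[["tumor_lymph_relation_mean"]], 3)
  expect_equal(f[["tumor_lymph_relation_sd"]], 0)
  expect_equal(f[["tumor_lymph_relation_frac_zero"]], 0)
  expect_equal(f[["tumor_lymph_relation_entropy"]], 0)

  m$counts[, "lymphocyte_neighbors"] <- c(0L, 0L, 0L, 4L)
  f <- interaction_features(m)
  expect_equal(f[["tumor_lymph_relation_mean"]], 1)
  expect_equal(f[["tumor_lymph_relation_frac_zero"]], 0.75)
  expect_equal(f[["tumor_lymph_relation_max"]], 4)
})

test_that("composite features use in-region counts", {
  set.seed(15)
  tum <- cbind(runif(10, 200, 800), runif(10, 200, 800))
  lym <- cbind(runif(5, 200, 800), runif(5, 200, 800))
  map <- toy_cellmap(tumor_xy = tum, lymph_xy = lym,
                     width = 1000, height = 1000,
                     core_margin = 100, band_width = 50)
  f <- composite_features(map, quiet = TRUE)
  expect_equal(f[["lymph_tumor_ratio_CT"]], 0.5)
  expect_equal(f[["total_count_CT"]], 15)
  expect_equal(f[["total_count_PT"]], 0)
  expect_true(is.na(f[["lymph_tumor_ratio_PT"]]))
})

test_that("the full extractor emits 246 deterministic, named features", {
  spec <- default_subtype_specs()$S1
  pts <- simulate_pointpattern(spec, 1200, 1200, seed = 21)
  map <- attach_nuclei(pts, spec, "ex", width = 1200, height = 1200,
                       seed = 22)
  img <- render_patch(map, 1200, 1200, seed = 23)
  f1 <- extract_features(map, img)
  f2 <- extract_features(map, img)
  expect_length(f1, 246)
  expect_identical(names(f1), feature_names())
  expect_identical(f1, f2)
})

test_that("registry category counts reproduce the printed taxonomy", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 246)
  counts <- table(reg$category)
  expect_equal(unname(counts[c("morphology", "histogram", "texture",
                               "color")]), c(20L, 14L, 62L, 54L),
               ignore_attr = TRUE)
  expect_equal(unname(counts["density_homogeneity"]), 28L,
               ignore_attr = TRUE)
  expect_equal(unname(counts["interaction"]), 64L, ignore_attr = TRUE)
  expect_equal(unname(counts["composite"]), 4L, ignore_attr = TRUE)
  expect_false(any(duplicated(reg$name)))
  # the documented headline features exist under their stated names
  expect_true(all(c("tumor_density_CT", "tumor_equivalent_diameter_mean",
                    "tumor_quadrat_sd_CT", "lymph_quadrat_mean_CT",
                    "lymph_quadrat_sd_CT", "tumor_lymph_relation_mean_CT")
                  %in% reg$name))
})

test_that("spatial features are invariant to translating map and ROIs", {
  spec <- default_subtype_specs()$S2
  pts <- simulate_pointpattern(spec, 1000, 1000, seed = 31)
  map <- attach_nuclei(pts, spec, "shift0", width = 1000, height = 1000,
                       seed = 32)
  shift <- 250
  map2 <- map
  map2$nuclei <- lapply(map$nuclei, function(n) {
    n$polygon <- n$polygon + shift
    n$centroid <- n$centroid + shift
    n
  })
  map2$rois <- lapply(map$rois, function(r) {
    r$polygon <- r$polygon + shift
    if (!is.null(r$inner)) r$inner <- r$inner + shift
    r
  })
  fl1 <- assign_roi(map, quiet = TRUE)
  fl2 <- assign_roi(map2, quiet = TRUE)
  spat1 <- spat2 <- numeric(0)
  for (reg in c("TUMOR_CORE", "TUMOR_PERIPHERY")) {
    for (cls in c("tumor", "lymph")) {
      spat1 <- c(spat1, density_homogeneity(map, reg, cls, flags = fl1))
      spat2 <- c(spat2, density_homogeneity(map2, reg, cls, flags = fl2))
    }
    for (r in c(50, 100)) {
      spat1 <- c(spat1, interaction_features(
        interaction_matrix(map, reg, r, fl1)))
      spat2 <- c(spat2, interaction_features(
        interaction_matrix(map2, reg, r, fl2)))
    }
  }
  spat1 <- c(spat1, composite_features(map, fl1, quiet = TRUE))
  spat2 <- c(spat2, composite_features(map2, fl2, quiet = TRUE))
  expect_equal(spat1, spat2, tolerance = 1e-9)
})
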