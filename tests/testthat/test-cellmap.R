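# Data model, GeoJSON round-trips and ROI assignment.

test_that("nucleus construction validates class, vertex count and geometry", {
  sq <- square_ring(5, 5, 2)
  expect_s3_class(nucleus(1, sq, "TUMOR"), "nucleus")
  expect_error(nucleus(1, sq, "stroma"), "cell_class")
  expect_error(nucleus(2, sq[1:2, ], "TUMOR"), "3 vertices")
  bowtie <- cbind(c(0, 5, 1, 4, 0), c(0, 0, 3, -2, 0))  # nonzero net area
  expect_error(nucleus(3, bowtie, "TUMOR"), "self-intersecting")
})

test_that("cellmap write/read round-trip is the identity on all fields", {
  nuclei <- list(
    nucleus(1, square_ring(100, 100, 10), "TUMOR"),
    nucleus(2, circle_ring(300, 200, 8, 16), "TUMOR"),
    nucleus(3, square_ring(500, 500, 6), "LYMPHOCYTE"),
    nucleus(4, square_ring(700, 300, 7), "OTHER"))
  map <- cellmap("spécimen-α", nuclei,
                 synthetic_rois(1000, 1000, core_margin = 150,
                                band_width = 80),
                 pixel_size_um = 0.5)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_cellmap(map, path)
  back <- read_cellmap(path)

  expect_identical(back$specimen_id, map$specimen_id)
  expect_identical(back$pixel_size_um, map$pixel_size_um)
  expect_length(back$nuclei, 4)
  for (i in 1:4) {
    expect_equal(back$nuclei[[i]]$polygon, map$nuclei[[i]]$polygon)
    expect_identical(back$nuclei[[i]]$cell_class, map$nuclei[[i]]$cell_class)
    expect_equal(back$nuclei[[i]]$centroid, map$nuclei[[i]]$centroid)
    expect_identical(back$nuclei[[i]]$id, map$nuclei[[i]]$id)
  }
  kinds <- vapply(back$rois, `[[`, "", "kind")
  expect_setequal(kinds, c("WHOLE_TUMOR", "TUMOR_CORE", "TUMOR_PERIPHERY"))
  per <- back$rois[[which(kinds == "TUMOR_PERIPHERY")]]
  expect_false(is.null(per$inner))  # annulus survives the round-trip

  # second round-trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".geojson")
  write_cellmap(back, path2)
  expect_identical(readLines(path, warn = FALSE),
                   readLines(path2, warn = FALSE))
})

test_that("written GeoJSON has one feature per nucleus and per ROI", {
  n <- 300
  nuclei <- lapply(seq_len(n), function(i)
    nucleus(i, square_ring(10 * (i %% 90) + 10, 10 * (i %/% 90) + 10, 4),
            "TUMOR", check = FALSE))
  map <- cellmap("many", nuclei, synthetic_rois(1000, 1000))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_cellmap(map, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, n + 3L)

  # empty map still yields a valid collection with only ROI features
  empty <- cellmap("empty", list(), synthetic_rois(500, 500, 125, 80))
  write_cellmap(empty, path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(gj$features, 3L)
  expect_length(read_cellmap(path)$nuclei, 0)
})

test_that("reading rejects missing cell_class and unknown classes", {
  map <- cellmap("x", list(nucleus(7, square_ring(50, 50, 4), "TUMOR")),
                 synthetic_rois(200, 200, core_margin = 60, band_width = 30))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_cellmap(map, path)
  txt <- readLines(path, warn = FALSE)
  expect_error(read_cellmap(withr::local_tempfile(lines = sub(
    "\"cell_class\":\"TUMOR\"", "\"cell_class\":\"stroma\"", txt))),
    "cell_class")
  expect_error(read_cellmap(withr::local_tempfile(lines = sub(
    "\"cell_class\":\"TUMOR\",", "", txt))), "cell_class")
})

test_that("assign_roi flags follow the region geometry and tie rule", {
  # whole 1000x1000, core = [100, 900]^2, periphery = outer 50 px band
  map <- toy_cellmap(tumor_xy = rbind(c(500, 500),   # core
                                      c(75, 500),    # between band and core
                                      c(25, 500),    # periphery band
                                      c(100, 100)),  # exactly on core corner
                     width = 1000, height = 1000,
                     core_margin = 100, band_width = 50)
  fl <- assign_roi(map)
  expect_equal(fl$whole, rep(TRUE, 4))
  expect_equal(fl$core, c(TRUE, FALSE, FALSE, TRUE))   # boundary is inside
  expect_equal(fl$periphery, c(FALSE, FALSE, TRUE, FALSE))
  # core implies whole; core and periphery exclusive
  expect_true(all(!fl$core | fl$whole))
  expect_true(!any(fl$core & fl$periphery))
})

test_that("nuclei outside all ROIs are flagged and reported, not dropped", {
  map <- toy_cellmap(tumor_xy = rbind(c(500, 500), c(1500, 1500)),
                     width = 1000, height = 1000)
  expect_message(fl <- assign_roi(map), "1 nuclei outside")
  expect_equal(nrow(fl), 2)
  expect_false(any(fl[2, c("whole", "core", "periphery")] == TRUE))
})

test_that("class counts are conserved through I/O", {
  map <- toy_cellmap(tumor_xy = rbind(c(100, 100), c(200, 200)),
                     lymph_xy = rbind(c(300, 300)),
                     other_xy = rbind(c(400, 400), c(450, 450), c(500, 500)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_cellmap(map, path)
  back <- read_cellmap(path)
  cls <- table(vapply(back$nuclei, `[[`, "", "cell_class"))
  expect_equal(unname(cls[c("TUMOR", "LYMPHOCYTE", "OTHER")]),
               c(2L, 1L, 3L), ignore_attr = TRUE)
})

test_that("clinical table reader enforces the header and value contracts", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(specimen_id = c("a", "b"), os_time = c(10, 5),
                   os_event = c(1, 0), stage = c("pT1", "pT2"),
                   grade = c("G1", "G2"), sex = c("female", "male"))
  write.csv(df, path, row.names = FALSE)
  expect_equal(read_clinical(path)$os_time, c(10, 5))
  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(read_clinical(path), "os_time")
  df$os_event[1] <- 2
  write.csv(df, path, row.names = FALSE)
  expect_error(read_clinical(path), "os_event")
})
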