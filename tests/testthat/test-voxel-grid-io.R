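test_that("voxel_grid enforces its geometric and intensity invariants", {
  a <- array(runif(3 * 4 * 5), dim = c(3, 4, 5))
  g <- voxel_grid(a, c(0.25, 0.11, 0.11), "membrane")
  expect_s3_class(g, "voxel_grid")
  expect_equal(unname(g$voxel_size), c(0.25, 0.11, 0.11))

  expect_error(voxel_grid(a[1:2, , ], c(0.25, 0.11, 0.11)), "3 planes")
  expect_error(voxel_grid(a - 1, c(0.25, 0.11, 0.11)), "non-negative")
  expect_error(voxel_grid(a, c(0.25, 0.11, 0.12)), "square")
  expect_error(voxel_grid(a, c(-0.25, 0.11, 0.11)), "positive")
  b <- a; b[1] <- NA
  expect_error(voxel_grid(b, c(0.25, 0.11, 0.11)))
  expect_error(voxel_grid(matrix(1, 4, 4), c(0.25, 0.11, 0.11)), "3D")
})

test_that("stack write/read round-trips data and voxel sizes losslessly", {
  g <- voxel_grid(array(sample(0:65535, 3 * 6 * 5, TRUE), dim = c(3, 6, 5)),
                  c(0.25, 0.11, 0.11), "particles")
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(g, path)
  back <- read_stack(path, "particles")
  expect_identical(back$data, g$data + 0)  # stored as numeric
  expect_equal(back$voxel_size, g$voxel_size)
  expect_identical(back$channel_name, "particles")
})

test_that("voxel-size override beats file metadata with a warning", {
  g <- voxel_grid(array(0, dim = c(3, 4, 4)), c(0.25, 0.11, 0.11))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(g, path)
  expect_warning(back <- read_stack(path, voxel_size = c(0.5, 0.2, 0.2)),
                 "override")
  expect_equal(unname(back$voxel_size), c(0.5, 0.2, 0.2))
})

test_that("metadata-free stacks are rejected unless a voxel size is supplied", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:4, function(i) matrix(runif(20), 4, 5))
  tiff::writeTIFF(pages, path)
  expect_error(read_stack(path), "voxel-size")
  g <- read_stack(path, voxel_size = c(0.25, 0.11, 0.11))
  expect_equal(dim(g$data), c(4L, 4L, 5L))
  expect_error(read_stack("does/not/exist.tif"), "not found")
})

test_that("2D-only TIFFs are rejected", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4)), path)
  expect_error(read_stack(path, voxel_size = c(0.25, 0.1, 0.1)), "3D stack")
})

test_that("an all-zero stack is a valid input yielding zero detections", {
  g <- voxel_grid(array(0, dim = c(5, 8, 8)), c(0.25, 0.11, 0.11))
  det <- detect_objects(g, detection_params(background_method = "none"))
  expect_identical(nrow(det$objects), 0L)
})

test_that("analysis reports round-trip through CSV + JSON exactly", {
  obj <- data.frame(object_id = 1:3,
                    x_um = c(1.25, 2.5, 3.75), y_um = c(0.5, 1, 2),
                    z_um = c(0.25, 0.5, 0.75),
                    region_label = c("intracellular", "membrane", "extracellular"),
                    integrated_intensity = c(48090.5, 96180.25, 144270),
                    n_particles = c(1L, 2L, 3L))
  rep0 <- uptake3d:::as_analysis_report_raw(
    obj, c(n_intracellular = 1, n_membrane = 2, n_extracellular = 3, n_total = 6),
    list(config_hash = "abc", calibration_i1 = 48090))
  prefix <- file.path(withr::local_tempdir(), "cell")
  paths <- write_report(rep0, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_report(prefix)
  expect_equal(back$per_object, rep0$per_object)
  expect_equal(unlist(back$per_cell), unlist(rep0$per_cell))

  # header-only CSV and all-zero totals for an empty report
  rep_empty <- uptake3d:::as_analysis_report_raw(
    obj[0, ], c(n_intracellular = 0, n_membrane = 0, n_extracellular = 0,
                n_total = 0), list())
  write_report(rep_empty, prefix)
  expect_identical(nrow(read_report(prefix)$per_object), 0L)
})

test_that("inconsistent report totals are rejected", {
  obj <- data.frame(object_id = 1L, x_um = 1, y_um = 1, z_um = 1,
                    region_label = "intracellular",
                    integrated_intensity = 48090, n_particles = 2L)
  expect_error(uptake3d:::as_analysis_report_raw(
    obj, c(n_intracellular = 1, n_membrane = 0, n_extracellular = 0,
           n_total = 1), list()), "does not match")
  expect_error(uptake3d:::as_analysis_report_raw(
    obj, c(n_intracellular = 2, n_membrane = 0, n_extracellular = 0,
           n_total = 1), list()), "inconsistent")
})

test_that("overlay colors objects by region and only inside masks", {
  p <- small_cell_params(data.frame(region = c("intra", "outside"), k = c(1, 1)),
                         seed = 11)
  sim <- generate_cell_stack(p)
  regions <- reconstruct_cell(sim$membrane)
  det <- detect_objects(subtract_background(sim$particles))
  det <- classify_objects(det, regions)
  path <- withr::local_tempfile(fileext = ".tif")
  vol <- write_overlay(sim$membrane, det, regions, path)
  expect_true(file.exists(path))
  # pure red voxels exactly where intracellular objects live
  red <- vol[, , , 1] > 0 & vol[, , , 2] == 0 & vol[, , , 3] == 0
  ids_intra <- det$objects$object_id[det$objects$region_label == "intracellular"]
  expect_identical(which(red), which(det$labels %in% ids_intra))
  # nothing colored outside objects and shell
  any_col <- vol[, , , 1] > 0 | vol[, , , 2] > 0 | vol[, , , 3] > 0
  allowed <- regions$membrane_shell | det$labels > 0
  expect_true(all(which(any_col) %in% which(allowed)))
})

test_that("region-mask and label exports encode their volumes faithfully", {
  p <- small_cell_params(data.frame(region = "intra", k = 1), seed = 8)
  sim <- generate_cell_stack(p)
  regions <- reconstruct_cell(sim$membrane)
  det <- detect_objects(subtract_background(sim$particles))
  dir <- withr::local_tempdir()
  write_regions_mask(regions, file.path(dir, "mask.tif"))
  m <- tiff::readTIFF(file.path(dir, "mask.tif"), all = TRUE, as.is = TRUE)
  expect_identical(sum(vapply(m, function(x) sum(x == 170), numeric(1))),
                   sum(regions$intracellular) + 0)
  write_labels(det, file.path(dir, "lab.tif"))
  l <- tiff::readTIFF(file.path(dir, "lab.tif"), all = TRUE, as.is = TRUE)
  expect_identical(sum(vapply(l, function(x) sum(x > 0), numeric(1))),
                   sum(det$labels > 0) + 0)
})
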