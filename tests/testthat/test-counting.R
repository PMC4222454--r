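test_that("objects are classified by the region containing their centroid", {
  p <- small_cell_params(data.frame(region = c("intra", "shell", "outside"),
                                    k = c(1, 1, 1)), seed = 42)
  sim <- generate_cell_stack(p)
  regions <- reconstruct_cell(sim$membrane)
  det <- detect_objects(subtract_background(sim$particles))
  det <- classify_objects(det, regions)
  expect_identical(nrow(det$objects), 3L)
  expect_setequal(det$objects$region_label,
                  c("intracellular", "membrane", "extracellular"))
  # match each detection to its true particle by position
  tr <- sim$truth$objects
  for (i in seq_len(nrow(tr))) {
    d2 <- (det$objects$x_um - tr$x_um[i])^2 + (det$objects$y_um - tr$y_um[i])^2 +
      (det$objects$z_um - tr$z_um[i])^2
    expect_identical(det$objects$region_label[which.min(d2)], tr$region[i])
  }
})

test_that("classification rejects mismatched geometries", {
  p <- small_cell_params(data.frame(region = "intra", k = 1), seed = 2)
  sim <- generate_cell_stack(p)
  regions <- reconstruct_cell(sim$membrane)
  det <- detect_objects(subtract_background(sim$particles))
  det$voxel_size <- det$voxel_size * 2
  expect_error(classify_objects(det, regions), "geometry mismatch")
})

test_that("counting rounds half-up against I1 and clamps at one particle", {
  i1 <- 48090
  expect_identical(count_particles(i1, i1), 1L)
  expect_identical(count_particles(0.4 * i1, i1), 1L)       # clamp
  expect_identical(count_particles(1.49 * i1, i1), 1L)
  expect_identical(count_particles(1.5 * i1, i1), 2L)       # half rounds up
  expect_identical(count_particles(c(2.2, 6.8, 10.1) * i1, i1), c(2L, 7L, 10L))
  expect_error(count_particles(i1, -5), "positive")
})

test_that("a merged agglomerate of seven unit spots counts as seven", {
  vs <- c(0.25, 0.11, 0.11)
  d <- c(17, 41, 41)
  cen <- (d - 1) * vs / 2
  # seven unit spots within a fraction of a PSF sigma: one detected object
  set.seed(13)
  pos <- sweep(matrix(runif(21, -0.03, 0.03), 7), 2, cen, "+")
  dat <- uptake3d:::add_psf_spots(array(0, dim = d), vs, pos,
                                  rep(48090, 7), c(0.15, 0.45))
  det <- detect_objects(voxel_grid(dat, vs, "p"),
                        detection_params(background_method = "none"))
  expect_identical(nrow(det$objects), 1L)
  expect_identical(count_particles(det$objects$integrated_intensity, 48090), 7L)
})

test_that("per-region totals sum the per-object counts and serialise consistently", {
  p <- small_cell_params(data.frame(
    region = c(rep("intra", 4), rep("shell", 2), rep("outside", 3)),
    k = c(3, 4, 1, 1, 1, 2, 1, 1, 1)), seed = 77)
  sim <- generate_cell_stack(p)
  regions <- reconstruct_cell(sim$membrane)
  det <- detect_objects(subtract_background(sim$particles))
  res <- summarize_cell(det, regions, sim$truth$i1_true)
  expect_identical(unname(res$totals["n_intracellular"]),
                   sum(res$objects$n_particles[res$objects$region_label == "intracellular"]))
  expect_identical(unname(res$totals["n_total"]), sum(res$objects$n_particles))
  expect_identical(unname(res$totals[1:3]), unname(sim$truth$totals))
  rep <- as_analysis_report(res, provenance = list(run = "test"))
  expect_identical(rep$per_cell[["n_total"]], unname(res$totals[["n_total"]]))
  expect_identical(rep$provenance$calibration_i1, sim$truth$i1_true)
})

test_that("an empty detection yields all-zero totals", {
  p <- small_cell_params(data.frame(region = character(0), k = integer(0)),
                         seed = 5)
  sim <- generate_cell_stack(p)
  regions <- reconstruct_cell(sim$membrane)
  det <- detect_objects(subtract_background(sim$particles))
  res <- summarize_cell(det, regions, 48090)
  expect_identical(unname(res$totals), c(0L, 0L, 0L, 0L))
})

test_that("total particle count does not depend on where region borders fall", {
  p <- small_cell_params(data.frame(region = c("intra", "intra", "shell", "outside"),
                                    k = c(2, 1, 1, 3)), seed = 19)
  sim <- generate_cell_stack(p)
  det <- detect_objects(subtract_background(sim$particles))
  mask <- make_cell_mask(smooth_membrane(sim$membrane))
  totals <- vapply(c(0.6, 1.4, 2.6), function(w) {
    reg <- suppressWarnings(build_regions(mask, w, sim$membrane$voxel_size))
    unname(summarize_cell(det, reg, 48090)$totals["n_total"])
  }, integer(1))
  expect_identical(totals, rep(totals[1], 3))
})

test_that("counts are invariant under joint intensity rescaling", {
  f <- generate_calibration_field(n_spots = 60, cv = 0.05,
                                  doublet_fraction = 0, seed = 23)
  p <- small_cell_params(data.frame(region = c("intra", "intra"), k = c(1, 4)),
                         seed = 23)
  sim <- generate_cell_stack(p)
  count_with <- function(c_scale) {
    cal <- calibrate_single_particle(
      voxel_grid(round(f$stack$data * c_scale), f$stack$voxel_size, "cal"))
    det <- detect_objects(subtract_background(
      voxel_grid(round(sim$particles$data * c_scale), sim$particles$voxel_size, "p")))
    sort(count_particles(det$objects$integrated_intensity, cal))
  }
  expect_identical(count_with(1), count_with(0.5))
})
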