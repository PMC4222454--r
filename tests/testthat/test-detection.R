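test_that("background subtraction: identity with method none, zeros on flat input", {
  g <- voxel_grid(array(runif(5 * 12 * 12) * 100, dim = c(5, 12, 12)),
                  c(0.25, 0.11, 0.11))
  expect_identical(subtract_background(g, detection_params(background_method = "none")),
                   g)
  flat <- voxel_grid(array(120, dim = c(5, 30, 30)), c(0.25, 0.11, 0.11))
  sub <- subtract_background(flat, detection_params())
  expect_true(all(sub$data == 0))
})

test_that("a uniform offset does not change measured spot intensities", {
  base <- spot_stack(dims = c(17, 61, 61), intensity = 48090)
  plus <- voxel_grid(base$data + 500, base$voxel_size, base$channel_name)
  p <- detection_params()
  i0 <- detect_objects(subtract_background(base, p), p)$objects$integrated_intensity
  i1 <- detect_objects(subtract_background(plus, p), p)$objects$integrated_intensity
  expect_length(i0, 1)
  expect_length(i1, 1)
  expect_equal(i1, i0, tolerance = 0.01)
})

test_that("a noiseless spot is found within half a voxel of its true position", {
  pos <- c(1.93, 3.02, 3.41)  # (z, y, x) µm
  g <- spot_stack(dims = c(17, 61, 61), pos_um = pos)
  det <- detect_objects(g, detection_params(background_method = "none"))
  expect_identical(nrow(det$objects), 1L)
  expect_lt(abs(det$objects$z_um - pos[1]), 0.25 / 2)
  expect_lt(abs(det$objects$y_um - pos[2]), 0.11 / 2)
  expect_lt(abs(det$objects$x_um - pos[3]), 0.11 / 2)
  # essentially the full flux is recovered on a noiseless stack
  expect_equal(det$objects$integrated_intensity, 48090, tolerance = 0.01)
})

test_that("well-separated spots resolve; overlapping spots merge additively", {
  vs <- c(0.25, 0.11, 0.11)
  mk <- function(sep_sigmas) {
    d <- c(17, 81, 81)
    cen <- (d - 1) * vs / 2
    off <- sep_sigmas * 0.15 / 2
    dat <- uptake3d:::add_psf_spots(array(0, dim = d), vs,
      rbind(cen + c(0, 0, -off), cen + c(0, 0, off)),
      c(48090, 48090), c(0.15, 0.45))
    voxel_grid(dat, vs, "particles")
  }
  # on a noiseless stack the support of each rasterised spot extends to the
  # 5-sigma truncation, so resolvable means separated beyond twice that
  far <- detect_objects(mk(12), detection_params(background_method = "none"))
  expect_identical(nrow(far$objects), 2L)
  near <- detect_objects(mk(0.8), detection_params(background_method = "none"))
  expect_identical(nrow(near$objects), 1L)
  expect_equal(near$objects$integrated_intensity, 2 * 48090, tolerance = 0.02)
})

test_that("with no aperture dilation, intensities sum exactly to the above-threshold mass", {
  set.seed(5)
  p <- detection_params(background_method = "none", measure_dilation_um = 0)
  vs <- c(0.25, 0.11, 0.11)
  d <- c(15, 91, 91)
  pos <- rbind(c(1.8, 2.2, 2.1), c(2.0, 7.5, 3.0), c(1.5, 4.8, 7.9))
  dat <- uptake3d:::add_psf_spots(array(0, dim = d), vs, pos,
                                  c(1, 2, 3) * 48090, c(0.15, 0.45))
  g <- voxel_grid(dat, vs, "particles")
  det <- detect_objects(g, p)
  expect_identical(nrow(det$objects), 3L)
  total_above <- sum(g$data[g$data > det$threshold])
  expect_equal(sum(det$objects$integrated_intensity), total_above, tolerance = 1e-12)
})

test_that("detection is equivariant under spatial mirroring", {
  set.seed(9)
  vs <- c(0.25, 0.11, 0.11)
  d <- c(15, 61, 61)
  pos <- rbind(c(1.6, 2.1, 2.4), c(2.1, 4.4, 3.9))
  dat <- uptake3d:::add_psf_spots(array(0, dim = d), vs, pos,
                                  c(48090, 96180), c(0.15, 0.45))
  g <- voxel_grid(dat, vs, "p")
  gm <- voxel_grid(dat[, , dim(dat)[3]:1], vs, "p")
  p <- detection_params(background_method = "none")
  a <- detect_objects(g, p)$objects
  b <- detect_objects(gm, p)$objects
  width <- (d[3] - 1) * vs[3]
  expect_equal(sort(a$x_um), sort(width - b$x_um), tolerance = 1e-9)
  expect_equal(sort(a$integrated_intensity), sort(b$integrated_intensity),
               tolerance = 1e-9)
})

test_that("small components below min_voxels are suppressed", {
  vs <- c(0.25, 0.11, 0.11)
  d <- c(15, 61, 61)
  a <- uptake3d:::add_psf_spots(array(0, dim = d), vs,
                                matrix(c(1.8, 3.3, 2.2), 1), 48090, c(0.15, 0.45))
  a[8, 31, 50] <- max(a)   # one isolated hot voxel
  det <- detect_objects(voxel_grid(a, vs),
                        detection_params(background_method = "none"))
  expect_identical(nrow(det$objects), 1L)   # hot voxel suppressed
  det2 <- detect_objects(voxel_grid(a, vs),
                         detection_params(background_method = "none",
                                          min_voxels = 1))
  expect_identical(nrow(det2$objects), 2L)
})

test_that("pure noise yields no detections at the default threshold", {
  hits <- vapply(1:20, function(s) {
    p <- scenario_params(cell_radius_um = 3, voxel_size = c(0.25, 0.2, 0.2),
                         pad_um = 1.5, seed = 1000 + s)
    sim <- generate_cell_stack(p)   # zero particles requested
    det <- detect_objects(subtract_background(sim$particles))
    nrow(det$objects)
  }, numeric(1))
  expect_lte(sum(hits > 0), 1)
})
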