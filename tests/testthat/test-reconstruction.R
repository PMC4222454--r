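test_that("zero-sigma smoothing is the identity and constants are unchanged", {
  g <- voxel_grid(array(runif(5 * 9 * 9) * 100, dim = c(5, 9, 9)),
                  c(0.25, 0.11, 0.11))
  expect_identical(smooth_membrane(g, reconstruction_params(smoothing_sigma_um = 0)),
                   g)
  const <- voxel_grid(array(7, dim = c(5, 9, 9)), c(0.25, 0.11, 0.11))
  sm <- smooth_membrane(const, reconstruction_params(smoothing_sigma_um = 0.3))
  expect_equal(sm$data, const$data, tolerance = 1e-12)
})

test_that("smoothing conserves total intensity of an interior blob", {
  d <- c(21, 41, 41)
  a <- array(0, dim = d)
  a[9:13, 17:25, 17:25] <- 500
  g <- voxel_grid(a, c(0.2, 0.1, 0.1))
  sm <- smooth_membrane(g, reconstruction_params(smoothing_sigma_um = 0.2))
  expect_lt(abs(sum(sm$data) - sum(a)) / sum(a), 0.001)
})

test_that("thresholding is invariant under positive intensity scaling", {
  set.seed(42)
  a <- array(rexp(6 * 20 * 20, 1 / 50), dim = c(6, 20, 20))
  a[3:4, 8:14, 8:14] <- a[3:4, 8:14, 8:14] + 600
  m1 <- make_cell_mask(voxel_grid(a, c(0.25, 0.2, 0.2)),
                       reconstruction_params(min_cell_volume_um3 = 0.01))
  m2 <- make_cell_mask(voxel_grid(a * 37.5, c(0.25, 0.2, 0.2)),
                       reconstruction_params(min_cell_volume_um3 = 0.01))
  expect_identical(which(m1), which(m2))
})

test_that("a noiseless spherical shell reconstructs to a solid ball of the right volume", {
  vs <- c(0.2, 0.2, 0.2)
  d <- rep(ceiling(2 * (8 + 1.5) / 0.2), 3)
  cen <- (d - 1) * vs / 2
  shell <- ball_mask(d, vs, cen, 8) & !ball_mask(d, vs, cen, 7.6)
  a <- array(0, dim = d)
  a[shell] <- 3000
  g <- voxel_grid(a, vs, "membrane")
  mask <- make_cell_mask(smooth_membrane(g))
  vol <- sum(mask) * prod(vs)
  expect_lt(abs(vol - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.05)
  # solid: no interior holes — the complement has one component (outside)
  comp <- uptake3d:::label3d_cpp(as.logical(!mask), dim(mask), 6L)
  expect_identical(attr(comp, "n_labels"), 1L)
})

test_that("an all-zero membrane stack raises 'no cell found'", {
  g <- voxel_grid(array(0, dim = c(5, 10, 10)), c(0.25, 0.2, 0.2))
  expect_error(make_cell_mask(g), "no cell found")
})

test_that("with two disjoint cells only the larger is analysed", {
  d <- c(20, 60, 60)
  vs <- c(0.25, 0.2, 0.2)
  big <- ball_mask(d, vs, c(2.5, 6, 3.5), 2.5)
  small <- ball_mask(d, vs, c(2.5, 6, 9.5), 1.2)
  a <- array(0, dim = d)
  a[big | small] <- 1000
  mask <- make_cell_mask(voxel_grid(a, vs),
                         reconstruction_params(smoothing_sigma_um = 0,
                                               min_cell_volume_um3 = 1))
  expect_true(all(mask[big]))
  expect_false(any(mask & small))
})

test_that("tiny debris below the volume floor is ignored, and an empty field errors", {
  d <- c(12, 30, 30); vs <- c(0.25, 0.2, 0.2)
  a <- array(0, dim = d)
  a[6, 15, 15] <- 1000   # one bright voxel: 0.01 µm³
  expect_error(make_cell_mask(voxel_grid(a, vs),
                              reconstruction_params(smoothing_sigma_um = 0,
                                                    min_cell_volume_um3 = 1)),
               "no cell found")
})

test_that("region masks partition the grid and realise the requested shell width", {
  vs <- c(0.1, 0.1, 0.1)
  d <- c(120, 120, 120)
  mask <- ball_mask(d, vs, (d - 1) * vs / 2, 4)
  reg <- build_regions(mask, 1.4, vs)
  expect_partition(reg)
  th <- shell_radial_thickness(reg, 60)
  expect_equal(mean(th), 1.4, tolerance = 0.2 / 1.4)
  # intracellular is an inner ball of roughly radius R - w/2
  vol_in <- sum(reg$intracellular) * prod(vs)
  expect_equal(vol_in, 4 / 3 * pi * (4 - 0.7)^3, tolerance = 0.08)
})

test_that("shell thickness is isotropic in physical units on anisotropic grids", {
  vs <- c(0.25, 0.1, 0.1)
  d <- c(56, 140, 140)
  cen <- (d - 1) * vs / 2
  mask <- ball_mask(d, vs, cen, 4.5)
  reg <- build_regions(mask, 1.4, vs)
  # transect along z through the center vs along x
  iz <- round(cen[1] / vs[1]) + 1; iy <- round(cen[2] / vs[2]) + 1
  ix <- round(cen[3] / vs[3]) + 1
  tz <- sum(reg$membrane_shell[, iy, ix] & ((seq_len(d[1]) - 1) * vs[1] > cen[1])) * vs[1]
  tx <- sum(reg$membrane_shell[iz, iy, ] & ((seq_len(d[3]) - 1) * vs[3] > cen[3])) * vs[3]
  expect_lt(abs(tz - tx), max(vs) + 1e-9)
})

test_that("one-voxel-scale shells reduce to single-voxel erosion on a cube", {
  vs <- c(0.2, 0.2, 0.2)
  d <- c(24, 24, 24)
  mask <- array(FALSE, dim = d)
  mask[6:19, 6:19, 6:19] <- TRUE
  reg <- suppressWarnings(build_regions(mask, 2 * 0.2, vs))
  inner <- array(FALSE, dim = d)
  inner[7:18, 7:18, 7:18] <- TRUE
  expect_identical(which(reg$intracellular), which(inner))
})

test_that("cells thinner than the shell width yield an empty intracellular mask with a warning", {
  vs <- c(0.2, 0.2, 0.2)
  mask <- array(FALSE, dim = c(10, 20, 20))
  mask[5:6, 5:16, 5:16] <- TRUE   # 0.4 µm thick slab
  expect_warning(reg <- build_regions(mask, 1.4, vs), "thinner")
  expect_identical(sum(reg$intracellular), 0L)
  expect_partition(reg)
})

test_that("growing the shell never shrinks it nor grows the other regions", {
  set.seed(7)
  for (i in 1:5) {
    d <- c(24, 32, 32)
    vs <- c(0.25, 0.15, 0.15)
    cen <- (d - 1) * vs / 2 + runif(3, -0.4, 0.4)
    mask <- ball_mask(d, vs, cen, runif(1, 1.2, 2.0))
    prev <- build_regions(mask, 0.6, vs)
    for (w in c(1.0, 1.4, 2.0)) {
      cur <- suppressWarnings(build_regions(mask, w, vs))
      expect_true(all(cur$membrane_shell[prev$membrane_shell]))
      expect_true(all(prev$intracellular[cur$intracellular]))
      expect_true(all(prev$extracellular[cur$extracellular]))
      expect_partition(cur)
      prev <- cur
    }
  }
})

test_that("distance-based regions match brute-force morphology on isotropic grids", {
  set.seed(11)
  vs <- c(0.2, 0.2, 0.2)
  d <- c(20, 20, 20)
  for (i in 1:3) {
    mask <- ball_mask(d, vs, (d - 1) * vs / 2 + runif(3, -0.3, 0.3),
                      runif(1, 0.9, 1.4))
    # w/2 chosen so no lattice distance ties it exactly
    w <- 0.81
    reg <- suppressWarnings(build_regions(mask, w, vs))
    # brute force: direct distance of every voxel to the nearest voxel of the
    # complementary set
    idx <- which(mask, arr.ind = TRUE)
    cdx <- which(!mask, arr.ind = TRUE)
    pm <- sweep(idx - 1, 2, vs, "*")
    pc <- sweep(cdx - 1, 2, vs, "*")
    mind2 <- function(a, b) apply(a, 1, function(p)
      min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2 + (b[, 3] - p[3])^2))
    din <- mind2(pm, pc)    # inside voxels: distance to outside
    dout <- mind2(pc, pm)   # outside voxels: distance to inside
    intra_bf <- which(mask)[sqrt(din) > w / 2]
    extra_bf <- which(!mask)[sqrt(dout) > w / 2]
    expect_identical(which(reg$intracellular), intra_bf)
    expect_identical(which(reg$extracellular), extra_bf)
  }
})
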