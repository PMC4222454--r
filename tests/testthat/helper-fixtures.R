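# shared fixtures: everything is generated in code at test time

# noise settings that make the camera model effectively exact
no_noise <- list(poisson_scale = 1e9, read_noise_sd = 0,
                 background_level = 0, camera_offset = 0)

# rasterise a solid ball mask on an anisotropic grid; center in µm (z, y, x)
ball_mask <- function(dims, voxel_size, center_um, radius_um) {
  zc <- (seq_len(dims[1]) - 1) * voxel_size[1]
  yc <- (seq_len(dims[2]) - 1) * voxel_size[2]
  xc <- (seq_len(dims[3]) - 1) * voxel_size[3]
  dz2 <- (zc - center_um[1])^2
  dy2 <- (yc - center_um[2])^2
  dx2 <- (xc - center_um[3])^2
  r2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  array(r2 <= radius_um^2, dim = dims)
}

# noiseless single-spot stack: one PSF spot of known total intensity
spot_stack <- function(dims = c(15, 33, 33), voxel_size = c(0.25, 0.11, 0.11),
                       pos_um = NULL, intensity = 48090,
                       psf = c(0.15, 0.45), offset = 0) {
  if (is.null(pos_um)) pos_um <- (dims - 1) * voxel_size / 2
  data <- uptake3d:::add_psf_spots(array(0, dim = dims), voxel_size,
                                   matrix(pos_um, 1), intensity, psf)
  voxel_grid(round(data) + offset, voxel_size, "particles")
}

# small default cell scenario used by several tests: radius 5 µm sphere at
# modest resolution so one generation + analysis runs in about a second
small_cell_params <- function(particles, seed = 1, ...) {
  scenario_params(cell_radius_um = 5, voxel_size = c(0.25, 0.15, 0.15),
                  particles = particles, seed = seed, ...)
}

expect_partition <- function(regions) {
  total <- sum(regions$intracellular) + sum(regions$membrane_shell) +
    sum(regions$extracellular)
  expect_identical(total, as.integer(prod(dim(regions$cell_mask))))
  expect_false(any(regions$intracellular & regions$membrane_shell))
  expect_false(any(regions$intracellular & regions$extracellular))
  expect_false(any(regions$membrane_shell & regions$extracellular))
}
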