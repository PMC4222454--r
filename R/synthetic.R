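#' Scenario parameters for synthetic two-channel cell stacks
#'
#' Describes a simulated uptake experiment: an analytic cell whose membrane
#' images as a bright shell, plus diffraction-limited particle spots of
#' roughly uniform unit brightness (k-particle agglomerates are k times as
#' bright), sampled onto an anisotropic voxel grid and corrupted by photon
#' (Poisson) and camera (Gaussian) noise.
#'
#' @param cell_shape `"sphere"`, `"ellipsoid"` or `"hemisphere"` (an adherent
#'   cell flattened on the coverslip). The sphere admits analytic oracles;
#'   the hemisphere is the realistic shape for endothelial cells.
#' @param cell_radius_um cell radius (for the ellipsoid, the equatorial
#'   radius; its axial semi-axis is `0.6 *` this).
#' @param membrane_thickness_um optical thickness of the rasterised membrane
#'   shell before blurring (default 0.4 µm; the stain layer plus PSF, not
#'   the 1.4 µm analysis region).
#' @param voxel_size `c(dz, dy, dx)` µm; default `c(0.25, 0.11, 0.11)` —
#'   250 nm optical sectioning over EMCCD pixels.
#' @param psf_sigma_um `c(lateral, axial)` Gaussian PSF sigmas (default
#'   `c(0.15, 0.45)`, approximating a 1.4 NA oil objective).
#' @param particle_unit_intensity total integrated intensity of one particle,
#'   raw units (default 48090).
#' @param particle_intensity_cv relative sd of the per-particle unit
#'   intensity (default 0.1).
#' @param membrane_intensity shell voxel intensity before blurring.
#' @param particles data frame with columns `region` (`"intra"`, `"shell"`,
#'   `"outside"`) and `k` (multiplicity >= 1), one row per object.
#' @param shell_width_um analysis shell width used to define placement
#'   regions (default 1.4; must match the reconstruction settings for
#'   ground-truth labels to be comparable).
#' @param placement_margin_um guard distance from region borders and stack
#'   edges when sampling positions (default 0.4 µm): ground-truth labels are
#'   only well defined away from the boundary the pipeline estimates itself.
#' @param min_separation_sigmas minimum spot separation in PSF-sigma units
#'   (default 4), so that objects stay resolvable.
#' @param noise list: `poisson_scale` (photons per intensity unit; smaller is
#'   noisier), `read_noise_sd` (camera noise, raw units), `background_level`
#'   (uniform optical background), `camera_offset` (bias added after the
#'   photon stage).
#' @param pad_um clear margin between cell and stack faces (default 2.5 µm).
#' @param seed integer; the same seed reproduces the stacks bit for bit.
#' @return a `scenario_params` list.
#' @examples
#' p <- scenario_params(cell_radius_um = 5, voxel_size = c(0.25, 0.15, 0.15),
#'                      particles = data.frame(region = c("intra", "outside"),
#'                                             k = c(3, 1)),
#'                      seed = 1)
#' sim <- generate_cell_stack(p)
#' sim$truth$totals
#' @export
scenario_params <- function(cell_shape = c("sphere", "ellipsoid", "hemisphere"),
                            cell_radius_um = 8,
                            membrane_thickness_um = 0.4,
                            voxel_size = c(0.25, 0.11, 0.11),
                            psf_sigma_um = c(0.15, 0.45),
                            particle_unit_intensity = 48090,
                            particle_intensity_cv = 0.1,
                            membrane_intensity = 3000,
                            particles = data.frame(region = character(0),
                                                   k = integer(0)),
                            shell_width_um = 1.4,
                            placement_margin_um = 0.4,
                            min_separation_sigmas = 4,
                            noise = list(poisson_scale = 0.2,
                                         read_noise_sd = 20,
                                         background_level = 20,
                                         camera_offset = 100),
                            pad_um = 2.5,
                            seed = 1L) {
  cell_shape <- match.arg(cell_shape)
  stopifnot(cell_radius_um > 0, membrane_thickness_um > 0,
            all(voxel_size > 0), all(psf_sigma_um > 0),
            particle_unit_intensity > 0, particle_intensity_cv >= 0,
            shell_width_um > 0, placement_margin_um >= 0)
  if (nrow(particles) > 0) {
    stopifnot(all(particles$region %in% c("intra", "shell", "outside")),
              all(particles$k >= 1))
  }
  noise <- utils::modifyList(list(poisson_scale = 0.2, read_noise_sd = 20,
                                  background_level = 20, camera_offset = 100),
                             as.list(noise))
  structure(list(cell_shape = cell_shape, cell_radius_um = cell_radius_um,
                 membrane_thickness_um = membrane_thickness_um,
                 voxel_size = as.numeric(voxel_size),
                 psf_sigma_um = as.numeric(psf_sigma_um),
                 particle_unit_intensity = particle_unit_intensity,
                 particle_intensity_cv = particle_intensity_cv,
                 membrane_intensity = membrane_intensity,
                 particles = particles, shell_width_um = shell_width_um,
                 placement_margin_um = placement_margin_um,
                 min_separation_sigmas = min_separation_sigmas,
                 noise = noise, pad_um = pad_um, seed = as.integer(seed)),
            class = "scenario_params")
}

# voxel-integrated separable Gaussian spots: adds spots of given total
# intensities at pos_um rows (z, y, x) to `data` in one pass. Voxel weights
# are exact Gaussian integrals over the voxel extent, so the sum over the
# stack of each spot equals its total intensity (up to the 5-sigma support
# truncation) — the premise of intensity-ratio counting.
add_psf_spots <- function(data, voxel_size, pos_um, total_intensity,
                          psf_sigma_um, truncate_sigmas = 5) {
  d <- dim(data)
  sig <- c(psf_sigma_um[2], psf_sigma_um[1], psf_sigma_um[1])  # (z, y, x)
  pos_um <- matrix(pos_um, ncol = 3)
  for (sp in seq_len(nrow(pos_um))) {
    wts <- vector("list", 3)
    rng <- vector("list", 3)
    ok <- TRUE
    for (ax in 1:3) {
      h <- voxel_size[ax]
      c0 <- pos_um[sp, ax]
      lo <- max(1L, floor((c0 - truncate_sigmas * sig[ax]) / h) + 1L)
      hi <- min(d[ax], ceiling((c0 + truncate_sigmas * sig[ax]) / h) + 1L)
      if (lo > hi) { ok <- FALSE; break }
      centers <- (seq(lo, hi) - 1) * h
      wts[[ax]] <- stats::pnorm(centers + h / 2, c0, sig[ax]) -
                   stats::pnorm(centers - h / 2, c0, sig[ax])
      rng[[ax]] <- lo:hi
    }
    if (!ok) next
    block <- outer(outer(wts[[1]], wts[[2]]), wts[[3]]) * total_intensity[sp]
    data[rng[[1]], rng[[2]], rng[[3]]] <-
      data[rng[[1]], rng[[2]], rng[[3]]] + block
  }
  data
}

# camera model: photon (Poisson) noise at `poisson_scale` photons per
# intensity unit, then offset and Gaussian read noise; digitised to integers
apply_camera_noise <- function(clean, noise) {
  d <- dim(clean)
  lam <- pmax(as.numeric(clean) + noise$background_level, 0) * noise$poisson_scale
  v <- stats::rpois(length(lam), lam) / noise$poisson_scale
  v <- v + noise$camera_offset + stats::rnorm(length(lam), 0, noise$read_noise_sd)
  array(pmin(pmax(round(v), 0), 65535), dim = d)
}

# signed distance (µm) from points (z, y, x µm) to the analytic cell surface:
# negative inside the cell
cell_signed_distance <- function(shape, center_um, radius_um, z_um, y_um, x_um) {
  dz <- z_um - center_um[1]; dy <- y_um - center_um[2]; dx <- x_um - center_um[3]
  if (shape == "sphere") {
    sqrt(dz^2 + dy^2 + dx^2) - radius_um
  } else if (shape == "ellipsoid") {
    # first-order signed distance: (rho - 1) / |grad rho| for the
    # normalised radius rho; exact on the surface, adequate nearby
    a <- radius_um; cc <- 0.6 * radius_um
    rho <- sqrt((dx / a)^2 + (dy / a)^2 + (dz / cc)^2)
    g <- sqrt((dx / a^2)^2 + (dy / a^2)^2 + (dz / cc^2)^2)
    ifelse(g == 0, -cc, rho * (rho - 1) / pmax(g, 1e-12))
  } else { # hemisphere sitting on a plane at z = center, dome pointing up
    r3 <- sqrt(dz^2 + dy^2 + dx^2)
    rl <- sqrt(dy^2 + dx^2)
    ifelse(dz >= 0,
           ifelse(r3 >= radius_um,
                  r3 - radius_um,                       # outside the dome
                  -pmin(radius_um - r3, dz)),           # inside: dome or base
           ifelse(rl <= radius_um, -dz,                 # below the base disk
                  sqrt((rl - radius_um)^2 + dz^2)))     # below, outside rim
  }
}

#' Generate a synthetic two-channel cell stack with ground truth
#'
#' The membrane channel is an analytic shell rasterised and blurred by the
#' PSF; the particle channel is a sum of PSF spots, one per object, with a
#' k-particle agglomerate built by summing k independently drawn unit
#' intensities. Both channels pass through the same Poisson + Gaussian
#' camera model. Positions are sampled uniformly within the requested region
#' class (relative to the analytic surface and the analysis shell width),
#' kept `placement_margin_um` clear of region borders and stack edges, and
#' separated by at least `min_separation_sigmas` PSF sigmas.
#'
#' @param params a [scenario_params()].
#' @return list with `membrane` and `particles` ([voxel_grid()]s) and
#'   `truth` (a `ground_truth`: per-object positions, region classes,
#'   multiplicities and drawn intensities; per-region totals; `i1_true`).
#' @export
generate_cell_stack <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  set.seed(params$seed)
  vs <- params$voxel_size
  R <- params$cell_radius_um
  zext <- if (params$cell_shape == "hemisphere") R + 2 * params$pad_um else 2 * (R + params$pad_um)
  ext <- c(zext, 2 * (R + params$pad_um), 2 * (R + params$pad_um))
  d <- pmax(ceiling(ext / vs), 3)
  center <- (d - 1) * vs / 2
  if (params$cell_shape == "hemisphere") center[1] <- params$pad_um

  # membrane channel: |signed distance| < thickness/2
  zc <- (seq_len(d[1]) - 1) * vs[1]
  yc <- (seq_len(d[2]) - 1) * vs[2]
  xc <- (seq_len(d[3]) - 1) * vs[3]
  gz <- array(zc, dim = d)
  gy <- array(rep(yc, each = d[1]), dim = d)
  gx <- array(rep(xc, each = d[1] * d[2]), dim = d)
  sd_surf <- array(cell_signed_distance(params$cell_shape, center, R,
                                        gz, gy, gx), dim = d)
  memb <- array(0, dim = d)
  memb[abs(sd_surf) < params$membrane_thickness_um / 2] <- params$membrane_intensity
  sig_vox <- c(params$psf_sigma_um[2], params$psf_sigma_um[1],
               params$psf_sigma_um[1]) / vs
  memb <- gauss_blur3d(memb, sig_vox)

  # particle placement
  np <- nrow(params$particles)
  pos <- matrix(NA_real_, np, 3)  # (z, y, x) µm
  drawn <- numeric(np)
  if (np > 0) {
    m <- params$placement_margin_um
    w2 <- params$shell_width_um / 2
    sep_ok <- function(p, placed) {
      if (nrow(placed) == 0) return(TRUE)
      dzs <- (p[1] - placed[, 1]) / params$psf_sigma_um[2]
      dys <- (p[2] - placed[, 2]) / params$psf_sigma_um[1]
      dxs <- (p[3] - placed[, 3]) / params$psf_sigma_um[1]
      all(sqrt(dzs^2 + dys^2 + dxs^2) >= params$min_separation_sigmas)
    }
    edge <- m + 3 * max(params$psf_sigma_um)
    for (i in seq_len(np)) {
      region <- params$particles$region[i]
      ok <- FALSE
      for (try in seq_len(20000L)) {
        p <- c(stats::runif(1, edge, (d[1] - 1) * vs[1] - edge),
               stats::runif(1, edge, (d[2] - 1) * vs[2] - edge),
               stats::runif(1, edge, (d[3] - 1) * vs[3] - edge))
        sdv <- cell_signed_distance(params$cell_shape, center, R, p[1], p[2], p[3])
        in_class <- switch(region,
          intra = sdv < -(w2 + m),
          shell = abs(sdv) < w2 - m,
          outside = sdv > w2 + m)
        if (in_class && sep_ok(p, pos[seq_len(i - 1), , drop = FALSE])) {
          pos[i, ] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place a particle of class '", region,
             "': region too small for the requested margin/separation ",
             "(is the cell thinner than the shell width?)")
    }
    for (i in seq_len(np)) {
      k <- params$particles$k[i]
      units <- stats::rnorm(k, params$particle_unit_intensity,
                            params$particle_intensity_cv * params$particle_unit_intensity)
      drawn[i] <- sum(pmax(units, 0))
    }
    part <- add_psf_spots(array(0, dim = d), vs, pos, drawn, params$psf_sigma_um)
  } else {
    part <- array(0, dim = d)
  }

  memb_noisy <- apply_camera_noise(memb, params$noise)
  part_noisy <- apply_camera_noise(part, params$noise)

  region_map <- c(intra = "intracellular", shell = "membrane",
                  outside = "extracellular")
  truth_obj <- data.frame(
    x_um = pos[, 3], y_um = pos[, 2], z_um = pos[, 1],
    region = if (np > 0) unname(region_map[params$particles$region]) else character(0),
    k = if (np > 0) as.integer(params$particles$k) else integer(0),
    drawn_intensity = drawn)
  totals <- c(
    n_intracellular = sum(truth_obj$k[truth_obj$region == "intracellular"]),
    n_membrane = sum(truth_obj$k[truth_obj$region == "membrane"]),
    n_extracellular = sum(truth_obj$k[truth_obj$region == "extracellular"]))
  truth <- structure(list(objects = truth_obj, totals = totals,
                          i1_true = params$particle_unit_intensity,
                          cell_center_um = center, seed = params$seed,
                          params = params),
                     class = "ground_truth")
  list(membrane = voxel_grid(memb_noisy, vs, "membrane"),
       particles = voxel_grid(part_noisy, vs, "particles"),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d object(s); true totals: %d intra / %d membrane / %d extra; i1 = %.6g (seed %d)\n",
              nrow(x$objects), x$totals[1], x$totals[2], x$totals[3],
              x$i1_true, x$seed))
  invisible(x)
}

#' Generate a synthetic coverslip calibration field
#'
#' Isolated particle spots on a flat background, at one focal plane, the way
#' a calibration sample is prepared by depositing particles on a coverslip.
#' Spots sit on a jittered lattice that enforces the minimum separation; a
#' given fraction are doublets with twice the unit intensity (two unit draws
#' summed).
#'
#' @param n_spots number of spots.
#' @param mu single-particle integrated intensity.
#' @param cv relative sd of the unit intensity.
#' @param doublet_fraction probability that a spot is a doublet.
#' @param multiplicities optional integer vector of length `n_spots` giving
#'   each spot's particle count explicitly (overrides `doublet_fraction`);
#'   a k-particle spot sums k independent unit-intensity draws.
#' @param voxel_size,psf_sigma_um,noise as in [scenario_params()].
#' @param seed integer seed.
#' @return list with `stack` (a [voxel_grid()]) and `truth` (data frame of
#'   spot positions, multiplicities and drawn intensities, plus `mu`).
#' @export
generate_calibration_field <- function(n_spots = 200, mu = 48090, cv = 0.1,
                                       doublet_fraction = 0.1,
                                       multiplicities = NULL,
                                       voxel_size = c(0.25, 0.11, 0.11),
                                       psf_sigma_um = c(0.15, 0.45),
                                       noise = list(poisson_scale = 0.2,
                                                    read_noise_sd = 20,
                                                    background_level = 20,
                                                    camera_offset = 100),
                                       seed = 1L) {
  stopifnot(n_spots >= 1, mu > 0, cv >= 0,
            doublet_fraction >= 0, doublet_fraction <= 1)
  noise <- utils::modifyList(list(poisson_scale = 0.2, read_noise_sd = 20,
                                  background_level = 20, camera_offset = 100),
                             as.list(noise))
  set.seed(seed)
  sep <- 4 * psf_sigma_um[1]
  # sparse deposition: spots several window-widths apart, as on a real
  # coverslip preparation, so no spot sits in another's background window
  pitch <- max(2.5 * sep, 3)
  ncol_l <- ceiling(sqrt(n_spots))
  nrow_l <- ceiling(n_spots / ncol_l)
  margin <- 1.0
  ext_y <- nrow_l * pitch + 2 * margin
  ext_x <- ncol_l * pitch + 2 * margin
  ext_z <- 2 * (4 * psf_sigma_um[2] + 0.5)
  d <- pmax(ceiling(c(ext_z, ext_y, ext_x) / voxel_size), 3)
  z0 <- (d[1] - 1) * voxel_size[1] / 2
  jit <- (pitch - sep) / 2

  idx <- seq_len(n_spots) - 1
  cy <- margin + (idx %/% ncol_l + 0.5) * pitch + stats::runif(n_spots, -jit, jit)
  cx <- margin + (idx %% ncol_l + 0.5) * pitch + stats::runif(n_spots, -jit, jit)
  cz <- z0 + stats::runif(n_spots, -0.1, 0.1)
  k <- if (!is.null(multiplicities)) {
    stopifnot(length(multiplicities) == n_spots, all(multiplicities >= 1))
    as.integer(multiplicities)
  } else {
    1L + stats::rbinom(n_spots, 1L, doublet_fraction)
  }
  drawn <- vapply(k, function(ki)
    sum(pmax(stats::rnorm(ki, mu, cv * mu), 0)), numeric(1))

  data <- add_psf_spots(array(0, dim = d), voxel_size, cbind(cz, cy, cx),
                        drawn, psf_sigma_um)
  data <- apply_camera_noise(data, noise)
  truth <- data.frame(x_um = cx, y_um = cy, z_um = cz, k = k,
                      drawn_intensity = drawn)
  list(stack = voxel_grid(data, voxel_size, "calibration"),
       truth = truth, mu = mu)
}

#' Generate a per-cell count table for a kinetics design
#'
#' Draws per-cell particle counts for a multi-condition, multi-timepoint
#' uptake experiment (the kind summarised as mean ± SEM bar charts over
#' n = 12–32 cells per point), so the statistics layer can be exercised
#' without any imaging.
#'
#' @param design data frame with columns `condition`, `time_h`, `n_cells`,
#'   `mean` and optionally `dispersion` (negative-binomial size; `Inf` or
#'   missing gives Poisson; `0` gives exactly-constant counts).
#' @param seed integer seed.
#' @return list with `counts` (data frame: `cell_id`, `condition`, `time_h`,
#'   `count`) and `design` (the input, the generating truth).
#' @export
generate_kinetics_dataset <- function(design, seed = 1L) {
  stopifnot(all(c("condition", "time_h", "n_cells", "mean") %in% names(design)))
  set.seed(seed)
  if (is.null(design$dispersion)) design$dispersion <- Inf
  rows <- lapply(seq_len(nrow(design)), function(i) {
    n <- design$n_cells[i]
    m <- design$mean[i]
    disp <- design$dispersion[i]
    cnt <- if (is.na(disp) || is.infinite(disp)) stats::rpois(n, m)
           else if (disp == 0) rep(round(m), n)
           else stats::rnbinom(n, size = disp, mu = m)
    data.frame(cell_id = sprintf("%s_t%g_c%02d", design$condition[i],
                                 design$time_h[i], seq_len(n)),
               condition = design$condition[i], time_h = design$time_h[i],
               count = as.integer(cnt))
  })
  list(counts = do.call(rbind, rows), design = design)
}
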