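#' Parameters for particle-spot detection
#'
#' @param background_method `"median"` (default): a slice-wise median filter
#'   estimates the slowly varying background, which is subtracted; `"none"`:
#'   identity.
#' @param median_radius_um median-filter window radius in µm (default 2 —
#'   several times the diffraction-limited spot size, so a spot cannot raise
#'   its own local background estimate and bias its integrated intensity).
#' @param detection_threshold_sigmas k in `threshold = background + k * noise
#'   sd` (default 5): voxels this far above the robust background are
#'   candidate particle signal.
#' @param min_voxels smallest accepted component size (default 4 — rejects
#'   isolated hot voxels while keeping sub-resolution particles, which span
#'   a few pixels laterally at 0.1–0.25 µm sampling).
#' @param connectivity 6 or 26 (default 26: diffraction-limited spots are
#'   compact blobs; face-only connectivity tends to split them across
#'   anisotropic z steps).
#' @param measure_dilation_um physical margin by which each object's support
#'   is grown (toward its nearest object, without overlap) before integrating
#'   intensity (default 0.7 µm). A fixed-size aperture captures the same
#'   fraction of a spot's flux regardless of its brightness, which keeps the
#'   intensity of a k-particle agglomerate at k times the single-particle
#'   intensity; `0` integrates over the thresholded voxels only.
#' @return a `detection_params` list.
#' @export
detection_params <- function(background_method = c("median", "none"),
                             median_radius_um = 2,
                             detection_threshold_sigmas = 5,
                             min_voxels = 4L,
                             connectivity = 26L,
                             measure_dilation_um = 0.7) {
  background_method <- match.arg(background_method)
  stopifnot(detection_threshold_sigmas > 0, min_voxels >= 1,
            connectivity %in% c(6L, 26L), median_radius_um > 0,
            measure_dilation_um >= 0)
  structure(list(background_method = background_method,
                 median_radius_um = median_radius_um,
                 detection_threshold_sigmas = detection_threshold_sigmas,
                 min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity),
                 measure_dilation_um = measure_dilation_um),
            class = "detection_params")
}

#' Subtract the image background from the particle channel
#'
#' With `background_method = "median"`, each z slice's background is estimated
#' by a median filter whose radius is given in physical units, then
#' subtracted; the result is clipped at zero. A robust estimate of the
#' residual noise sd (MAD of the pre-clip residuals) is attached as attribute
#' `noise_sd` for use by [detect_objects()].
#'
#' @param grid a [voxel_grid()].
#' @param params a [detection_params()].
#' @return a background-subtracted [voxel_grid()].
#' @export
subtract_background <- function(grid, params = detection_params()) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (params$background_method == "none") return(grid)
  r <- max(1L, as.integer(round(params$median_radius_um / grid$voxel_size["dx"])))
  d <- dim(grid$data)
  resid <- grid$data
  is_int16 <- max(grid$data) <= 65535 && all(grid$data == floor(grid$data))
  medfilt <- if (is_int16) {
    # sigma-clipped background: particle pixels (several sd above the global
    # background) are excluded from the window so spots cannot raise their
    # own background estimate
    g <- as.numeric(grid$data)
    cap <- floor(stats::median(g) + 3 * stats::mad(g))
    function(m) medfilt2d_hist_cpp(matrix(as.integer(m), nrow(m)), r, cap)
  } else {
    function(m) medfilt2d_cpp(m, r)
  }
  for (i in seq_len(d[1]))
    resid[i, , ] <- grid$data[i, , ] - medfilt(grid$data[i, , ])
  noise_sd <- stats::mad(resid, center = stats::median(resid))
  out <- voxel_grid(pmax(array(resid, dim = d), 0), grid$voxel_size, grid$channel_name)
  attr(out$data, "noise_sd") <- noise_sd
  # unclipped residuals: zero-clipping rectifies noise and would bias any
  # aperture sum upward, so integration uses these when available
  attr(out$data, "residual") <- as.numeric(resid)
  out
}

# robust background level and noise sd of a (possibly zero-clipped) stack.
# After clipping, more than half the voxels can be exactly 0, making the MAD
# collapse; the positive residuals are then the upper half of the noise
# distribution, whose median sits at qnorm(0.75) * sd.
robust_noise <- function(x, attr_sd = NULL) {
  bg <- stats::median(x)
  sd <- if (!is.null(attr_sd) && is.finite(attr_sd) && attr_sd > 0) attr_sd
        else stats::mad(x, center = bg)
  if (sd <= 0) {
    pos <- x[x > bg]
    sd <- if (length(pos)) stats::median(pos - bg) / stats::qnorm(0.75) else 0
  }
  c(background = bg, sd = sd)
}

#' Detect particle objects in a background-subtracted stack
#'
#' Voxels above `background + k * sd` (both estimated robustly, by median and
#' MAD) are grouped into 3D connected components; components smaller than
#' `min_voxels` are dropped. Each surviving component is one detected object —
#' a single particle or an agglomerate — with an intensity-weighted centroid
#' in µm and an integrated intensity measured by aperture photometry: the
#' component dilated by `measure_dilation_um` (each voxel assigned to its
#' nearest object, so apertures never overlap), summed on unclipped
#' residuals, minus a local background level taken from a 0.5 µm annulus
#' around the aperture.
#'
#' Objects are sorted by centroid (z, y, x) and given stable ids 1..n.
#'
#' @param grid background-subtracted [voxel_grid()] (see
#'   [subtract_background()]).
#' @param params a [detection_params()].
#' @return a `detected_objects` object: `$objects` is a data frame with
#'   columns `object_id`, `x_um`, `y_um`, `z_um`, `voxel_count`,
#'   `integrated_intensity`, `region_label` (initially `"unassigned"`),
#'   `n_particles` (initially `NA`); `$labels` is the integer label volume
#'   (thresholded support); `$threshold` the applied threshold.
#' @export
detect_objects <- function(grid, params = detection_params()) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  vs <- grid$voxel_size
  nz <- robust_noise(as.numeric(grid$data), attr(grid$data, "noise_sd"))
  thr <- nz["background"] + params$detection_threshold_sigmas * nz["sd"]
  above <- grid$data > thr
  empty <- function() {
    obj <- data.frame(object_id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), voxel_count = integer(0),
                      integrated_intensity = numeric(0),
                      region_label = character(0), n_particles = integer(0),
                      stringsAsFactors = FALSE)
    structure(list(objects = obj, labels = array(0L, dim = d),
                   threshold = unname(thr), voxel_size = vs, dim = d),
              class = "detected_objects")
  }
  if (!any(above)) return(empty())

  lab <- label3d_cpp(as.logical(above), d, params$connectivity)
  n_raw <- attr(lab, "n_labels")
  sizes <- tabulate(lab[lab > 0L], n_raw)
  keep <- which(sizes >= params$min_voxels)
  if (length(keep) == 0) return(empty())
  remap <- integer(n_raw)

  # measurement support: dilate kept components by a fixed physical margin,
  # each voxel claimed by its nearest component (EDT with site propagation)
  keep_flag <- sizes >= params$min_voxels
  lab_kept <- lab
  posv <- lab > 0L
  lab_kept[posv][!keep_flag[lab[posv]]] <- 0L
  if (params$measure_dilation_um > 0) {
    ed <- edt3d_cpp(as.logical(lab_kept > 0L), d, vs)
    meas_lab <- integer(length(lab_kept))
    inside <- ed$dist2 <= params$measure_dilation_um^2 & ed$nearest > 0L
    meas_lab[inside] <- lab_kept[ed$nearest[inside]]
  } else {
    meas_lab <- lab_kept
  }

  vals <- as.numeric(grid$data)
  resid <- attr(grid$data, "residual")
  vals_meas <- if (!is.null(resid)) resid else vals
  core_idx <- which(lab_kept > 0L)
  core_by <- split(core_idx, lab_kept[core_idx])
  meas_idx <- which(meas_lab > 0L)
  meas_sum <- vapply(split(vals_meas[meas_idx], meas_lab[meas_idx]), sum, numeric(1))
  if (params$measure_dilation_um > 0) {
    # aperture photometry: whatever local background level survives the
    # median-filter subtraction (its estimate is slightly biased inside a
    # spot's own window) is measured in an annulus just outside each
    # object's aperture and removed, scaled by the aperture size
    annw <- 0.5
    ann <- ed$dist2 > params$measure_dilation_um^2 &
           ed$dist2 <= (params$measure_dilation_um + annw)^2 & ed$nearest > 0L
    ann_idx <- which(ann)
    ann_lab <- lab_kept[ed$nearest[ann_idx]]
    ann_med <- vapply(split(vals_meas[ann_idx], ann_lab), stats::median, numeric(1))
    n_ap <- vapply(split(meas_idx, meas_lab[meas_idx]), length, numeric(1))
    common <- intersect(names(meas_sum), names(ann_med))
    meas_sum[common] <- meas_sum[common] - n_ap[common] * ann_med[common]
  }
  rows <- lapply(as.character(keep), function(l) {
    vox <- core_by[[l]]
    w <- vals[vox]
    zyx <- cbind((vox - 1L) %% d[1],
                 ((vox - 1L) %/% d[1]) %% d[2],
                 (vox - 1L) %/% (d[1] * d[2]))
    cen <- colSums(zyx * w) / sum(w) * vs     # (z, y, x) µm
    data.frame(x_um = cen[3], y_um = cen[2], z_um = cen[1],
               voxel_count = length(vox),
               integrated_intensity = unname(meas_sum[l]))
  })
  obj <- do.call(rbind, rows)
  ord <- order(obj$z_um, obj$y_um, obj$x_um)
  obj <- obj[ord, , drop = FALSE]
  obj$object_id <- seq_len(nrow(obj))
  remap[keep[ord]] <- seq_len(nrow(obj))
  obj$region_label <- "unassigned"
  obj$n_particles <- NA_integer_
  obj <- obj[, c("object_id", "x_um", "y_um", "z_um", "voxel_count",
                 "integrated_intensity", "region_label", "n_particles")]
  rownames(obj) <- NULL
  lab_out <- array(0L, dim = d)
  nzv <- lab > 0L
  lab_out[nzv] <- remap[lab[nzv]]
  structure(list(objects = obj, labels = lab_out, threshold = unname(thr),
                 voxel_size = vs, dim = d),
            class = "detected_objects")
}

#' @export
print.detected_objects <- function(x, ...) {
  cat(sprintf("<detected_objects> %d object(s), threshold %.4g\n",
              nrow(x$objects), x$threshold))
  if (nrow(x$objects)) {
    cat(sprintf("  integrated intensity: median %.4g, range [%.4g, %.4g]\n",
                stats::median(x$objects$integrated_intensity),
                min(x$objects$integrated_intensity),
                max(x$objects$integrated_intensity)))
  }
  invisible(x)
}
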