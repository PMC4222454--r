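#' Construct a single-channel 3D intensity grid
#'
#' A `voxel_grid` couples a 3D intensity array with the physical size of its
#' voxels, so that all downstream morphology (smoothing, distance transforms,
#' centroids) can work in micrometres rather than voxel indices. Confocal
#' z-stacks are anisotropic — the optical-section spacing (typically 0.25 µm)
#' differs from the camera pixel size — which is why the physical sizes travel
#' with the data.
#'
#' @param data numeric 3D array indexed `[z, y, x]`, non-negative finite
#'   intensities in raw camera units. No rescaling is applied.
#' @param voxel_size numeric length-3 vector `c(dz, dy, dx)` in µm. Pixels
#'   must be square (`dy == dx`).
#' @param channel_name short label for the channel (e.g. `"membrane"`,
#'   `"particles"`).
#'
#' @details The physical coordinate of voxel `(z, y, x)` (1-based indices) is
#' `(index - 1) * voxel_size`, i.e. the origin sits at the centre of the first
#' voxel. Stacks must have at least 3 planes in z: a 3D reconstruction is
#' meaningless on a single section.
#'
#' @return An object of class `voxel_grid` with elements `data`, `voxel_size`
#'   (named `dz`, `dy`, `dx`) and `channel_name`.
#' @seealso [read_stack()], [smooth_membrane()], [detect_objects()]
#' @export
voxel_grid <- function(data, voxel_size, channel_name = "unnamed") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [z, y, x]")
  if (dim(data)[1] < 3L)
    stop("stack must have at least 3 planes in z (got ", dim(data)[1], ")")
  if (anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite and non-missing")
  if (any(data < 0))
    stop("intensities must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths c(dz, dy, dx) in µm")
  if (abs(voxel_size[2] - voxel_size[3]) > 1e-9 * voxel_size[2])
    stop("pixels must be square: dy (", voxel_size[2], ") != dx (", voxel_size[3], ")")
  names(voxel_size) <- c("dz", "dy", "dx")
  structure(
    list(data = data, voxel_size = voxel_size,
         channel_name = as.character(channel_name)[1]),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> channel '%s': %d x %d x %d voxels (z,y,x)\n",
              x$channel_name, d[1], d[2], d[3]))
  cat(sprintf("  voxel size: dz=%.4g, dy=%.4g, dx=%.4g µm (extent %.3g x %.3g x %.3g µm)\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              d[1] * x$voxel_size[1], d[2] * x$voxel_size[2], d[3] * x$voxel_size[3]))
  cat(sprintf("  intensity range: [%.6g, %.6g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# physical extent along (z, y, x), µm
grid_extent_um <- function(grid) dim(grid$data) * grid$voxel_size

# convert a physical position (x, y, z µm) to the nearest 1-based voxel index
# (z, y, x); positions are clamped into the grid.
um_to_voxel <- function(grid, x_um, y_um, z_um) {
  vs <- grid$voxel_size
  d <- dim(grid$data)
  iz <- pmin(pmax(round(z_um / vs[1]) + 1, 1), d[1])
  iy <- pmin(pmax(round(y_um / vs[2]) + 1, 1), d[2])
  ix <- pmin(pmax(round(x_um / vs[3]) + 1, 1), d[3])
  cbind(z = iz, y = iy, x = ix)
}

same_geometry <- function(a_dim, a_vs, b_dim, b_vs, tol = 1e-9) {
  identical(as.integer(a_dim), as.integer(b_dim)) &&
    all(abs(a_vs - b_vs) <= tol * pmax(a_vs, b_vs))
}
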