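#' Read a multi-page TIFF z-stack as a voxel grid
#'
#' Reads a single-channel 3D stack (one page per optical section). Voxel sizes
#' are taken, in order of precedence, from (1) the `voxel_size` argument
#' (config override — a warning is emitted when it overrides file metadata),
#' (2) a JSON sidecar `<path>.json` as written by [write_stack()], (3)
#' ImageJ-style TIFF metadata (a `spacing=` entry in the image description for
#' dz, plus x/y resolution tags for the pixel size). Plain TIFFs without any
#' of these are rejected: analysing a stack at a silently wrong physical scale
#' is the worst possible failure mode.
#'
#' @param path path to a multi-page TIFF / OME-TIFF file.
#' @param expected_channel channel label recorded on the returned grid.
#' @param voxel_size optional `c(dz, dy, dx)` in µm, overriding file metadata.
#' @return A [voxel_grid()]. Intensities are returned as stored (integer TIFF
#'   samples are not rescaled to `[0, 1]`).
#' @export
read_stack <- function(path, expected_channel = "unnamed", voxel_size = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 3L)
    stop("'", path, "' has ", length(pages),
         " page(s); a 3D stack with >= 3 z planes is required")
  if (length(dim(pages[[1]])) == 3L && dim(pages[[1]])[3] > 1L)
    stop("'", path, "' has multiple samples per pixel; supply one channel per file")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(length(pages), ny, nx))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]

  meta_vs <- stack_metadata_voxel_size(path, pages[[1]])
  if (!is.null(voxel_size)) {
    if (!is.null(meta_vs) && !isTRUE(all.equal(as.numeric(voxel_size), as.numeric(meta_vs))))
      warning("voxel-size override c(", paste(signif(voxel_size, 6), collapse = ", "),
              ") replaces file metadata c(", paste(signif(meta_vs, 6), collapse = ", "), ")")
    vs <- voxel_size
  } else if (!is.null(meta_vs)) {
    vs <- meta_vs
  } else {
    stop("'", path, "' carries no voxel-size metadata; supply `voxel_size` ",
         "(config key voxel_size_um) explicitly")
  }
  voxel_grid(data, vs, expected_channel)
}

# sidecar JSON first, then ImageJ description (spacing= + resolution tags)
stack_metadata_voxel_size <- function(path, first_page) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) return(as.numeric(meta$voxel_size_um))
  }
  att <- attributes(first_page)
  desc <- att$description
  if (is.null(desc)) return(NULL)
  m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
  if (length(m) < 2L) return(NULL)
  dz <- as.numeric(m[2])
  if (is.null(att$x.resolution) || att$x.resolution <= 0) return(NULL)
  dx <- 1 / att$x.resolution
  dy <- if (!is.null(att$y.resolution) && att$y.resolution > 0) 1 / att$y.resolution else dx
  c(dz, dy, dx)
}

#' Write a voxel grid as a multi-page TIFF with a metadata sidecar
#'
#' Intensities are stored as 8- or 16-bit integer samples in raw units
#' (camera-native range); a JSON sidecar `<path>.json` records the voxel
#' sizes and channel name so that [read_stack()] round-trips losslessly.
#'
#' @param grid a [voxel_grid()]; intensities must be integers representable at
#'   the requested bit depth.
#' @param path output TIFF path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_stack <- function(grid, path, bits = 16L) {
  stopifnot(inherits(grid, "voxel_grid"), bits %in% c(8L, 16L))
  mx <- 2^bits - 1
  d <- grid$data
  if (max(d) > mx)
    stop("intensities exceed the ", bits, "-bit range (max ", max(d), " > ", mx, ")")
  if (any(abs(d - round(d)) > 1e-6))
    stop("intensities must be integral for integer TIFF storage")
  pages <- lapply(seq_len(dim(d)[1]), function(i) d[i, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "deflate")
  jsonlite::write_json(
    list(voxel_size_um = as.numeric(grid$voxel_size),
         channel_name = grid$channel_name,
         axes = "zyx", units = "um"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an analysis report (per-object CSV + per-cell JSON sidecar)
#'
#' @param report an `analysis_report` from [as_analysis_report()].
#' @param path_prefix output prefix; writes `<prefix>_objects.csv` and
#'   `<prefix>_summary.json`.
#' @return invisibly, the two paths written.
#' @export
write_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "analysis_report"))
  csv <- paste0(path_prefix, "_objects.csv")
  js <- paste0(path_prefix, "_summary.json")
  utils::write.csv(report$per_object, csv, row.names = FALSE)
  jsonlite::write_json(
    list(per_cell = as.list(report$per_cell), provenance = report$provenance),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(objects = csv, summary = js))
}

#' Read back a report written by [write_report()]
#' @param path_prefix prefix used when writing.
#' @return an `analysis_report`.
#' @export
read_report <- function(path_prefix) {
  per_object <- utils::read.csv(paste0(path_prefix, "_objects.csv"),
                                stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path_prefix, "_summary.json"),
                              simplifyVector = TRUE)
  as_analysis_report_raw(per_object, unlist(side$per_cell), side$provenance)
}

#' Render a pseudo-coloured RGB overlay of the segmentation
#'
#' Writes an RGB stack in which the membrane shell appears in one colour
#' (default cyan) and each detected object is painted over its voxels in a
#' colour keyed by its subcellular region — the standard presentation for
#' uptake experiments (intracellular red or magenta, membrane-associated
#' yellow).
#'
#' @param membrane membrane-channel [voxel_grid()] (used for geometry only).
#' @param detection a `detected_objects` result carrying the label volume.
#' @param regions a `cell_regions` object.
#' @param path output TIFF path (RGB, 8-bit).
#' @param colors named list of colours for `membrane`, `intracellular`,
#'   `membrane_assoc`, `extracellular` (any R colour specification).
#' @return invisibly, the RGB array that was written (z, y, x, rgb).
#' @export
write_overlay <- function(membrane, detection, regions, path,
                          colors = list(membrane = "cyan",
                                        intracellular = "red",
                                        membrane_assoc = "yellow",
                                        extracellular = "gray")) {
  stopifnot(inherits(detection, "detected_objects"), inherits(regions, "cell_regions"))
  d <- dim(membrane$data)
  if (!same_geometry(d, membrane$voxel_size, dim(regions$membrane_shell), regions$voxel_size))
    stop("membrane grid and regions have different geometry")
  rgb_of <- function(col) as.numeric(grDevices::col2rgb(col)) / 255
  vol <- array(0, dim = c(d, 3L))
  shell_col <- rgb_of(colors$membrane)
  for (ch in 1:3) {
    plane <- array(0, dim = d)
    plane[regions$membrane_shell] <- shell_col[ch]
    vol[, , , ch] <- plane
  }
  obj <- detection$objects
  lab <- detection$labels
  if (nrow(obj) > 0) {
    key <- c(intracellular = "intracellular", membrane = "membrane_assoc",
             extracellular = "extracellular", unassigned = "extracellular")
    for (i in seq_len(nrow(obj))) {
      col <- rgb_of(colors[[key[[as.character(obj$region_label[i])]]]])
      vox <- which(lab == obj$object_id[i])
      for (ch in 1:3) {
        plane <- vol[, , , ch]
        plane[vox] <- col[ch]
        vol[, , , ch] <- plane
      }
    }
  }
  pages <- lapply(seq_len(d[1]), function(i) vol[i, , , , drop = TRUE])
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  invisible(vol)
}

#' Export the region masks as an 8-bit TIFF
#'
#' Encodes extracellular as 0, membrane shell as 85 and intracellular as 170
#' — a three-level stack that renders readably in any viewer.
#'
#' @param regions a `cell_regions`.
#' @param path output TIFF path.
#' @export
write_regions_mask <- function(regions, path) {
  stopifnot(inherits(regions, "cell_regions"))
  enc <- array(0, dim = dim(regions$cell_mask))
  enc[regions$membrane_shell] <- 85
  enc[regions$intracellular] <- 170
  pages <- lapply(seq_len(dim(enc)[1]), function(i) enc[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  invisible(path)
}

#' Export the detection label volume as a 16-bit TIFF
#'
#' Background is 0; each object's voxels carry its `object_id`.
#'
#' @param detection a `detected_objects` result.
#' @param path output TIFF path.
#' @export
write_labels <- function(detection, path) {
  stopifnot(inherits(detection, "detected_objects"))
  lab <- detection$labels
  pages <- lapply(seq_len(dim(lab)[1]), function(i) lab[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  invisible(path)
}
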