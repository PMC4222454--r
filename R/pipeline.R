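#' Read and validate a run configuration
#'
#' The configuration is plain YAML with up to four blocks —
#' `reconstruction`, `detection`, `calibration`, `io` — whose keys map 1:1
#' onto [reconstruction_params()], [detection_params()],
#' [calibrate_single_particle()] and the I/O options (`voxel_size_um`,
#' `overlay_colors`). Unknown blocks or keys are rejected rather than
#' silently ignored: a typo in a threshold name must not change an analysis.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return a `run_config` list with `reconstruction`, `detection`,
#'   `calibration` (list of min_spots/trim_sd/max_iter), `io`, and a
#'   `config_hash` fingerprint used in report provenance.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_blocks <- c("reconstruction", "detection", "calibration", "io")
  extra <- setdiff(names(raw), known_blocks)
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "))
  take <- function(block, allowed) {
    b <- raw[[block]]
    if (is.null(b)) return(list())
    bad <- setdiff(names(b), allowed)
    if (length(bad))
      stop("unknown key(s) in config block '", block, "': ",
           paste(bad, collapse = ", "))
    b
  }
  rec <- do.call(reconstruction_params,
                 take("reconstruction",
                      c("smoothing_sigma_um", "threshold_method", "fixed_threshold",
                        "shell_width_um", "min_cell_volume_um3")))
  det <- do.call(detection_params,
                 take("detection",
                      c("background_method", "median_radius_um",
                        "detection_threshold_sigmas", "min_voxels", "connectivity",
                        "measure_dilation_um")))
  cal <- utils::modifyList(list(min_spots = 50, trim_sd = 2.5, max_iter = 10),
                           take("calibration", c("min_spots", "trim_sd", "max_iter")))
  io <- utils::modifyList(list(voxel_size_um = NULL, overlay_colors = NULL),
                          take("io", c("voxel_size_um", "overlay_colors")))
  cfg <- list(reconstruction = rec, detection = det, calibration = cal, io = io)
  ser <- jsonlite::toJSON(list(reconstruction = unclass(rec),
                               detection = unclass(det),
                               calibration = cal, io = io),
                          auto_unbox = TRUE, null = "null")
  cfg$config_hash <- sprintf("%08x", sum(utf8ToInt(as.character(ser)) *
                                           (seq_along(utf8ToInt(as.character(ser))) %% 251 + 1)) %% .Machine$integer.max)
  class(cfg) <- "run_config"
  cfg
}

#' Quantify nanoparticle uptake for one cell
#'
#' The full analysis chain on in-memory grids: reconstruct the cell and its
#' regions from the membrane channel, background-subtract and detect objects
#' in the particle channel, classify each object by region, convert its
#' intensity to a particle count against the calibration, and total per
#' region. Deterministic: the same inputs and configuration always give the
#' same report.
#'
#' @param membrane,particles [voxel_grid()]s sharing one geometry.
#' @param cal a `calibration_result` or plain I1 value.
#' @param config a `run_config` (default: all defaults).
#' @return a `cell_uptake_result` (see [summarize_cell()]), with the
#'   intermediate `cell_regions` attached as `$regions`.
#' @export
quantify_cell <- function(membrane, particles, cal,
                          config = read_run_config()) {
  stopifnot(inherits(membrane, "voxel_grid"), inherits(particles, "voxel_grid"))
  if (!same_geometry(dim(membrane$data), membrane$voxel_size,
                     dim(particles$data), particles$voxel_size))
    stop("[reconstruction] membrane and particle stacks differ in geometry")
  regions <- with_stage("reconstruction", reconstruct_cell(membrane, config$reconstruction))
  sub <- with_stage("detection", subtract_background(particles, config$detection))
  det <- with_stage("detection", detect_objects(sub, config$detection))
  res <- with_stage("counting", summarize_cell(det, regions, cal))
  res$regions <- regions
  res
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the file-based quantification pipeline
#'
#' File-in/file-out orchestration around [quantify_cell()]: reads the two
#' channel TIFFs and the calibration JSON, runs the analysis, and writes the
#' per-object CSV, the per-cell JSON summary and the pseudo-coloured RGB
#' overlay into `out_dir`.
#'
#' @param membrane_path,particles_path single-channel TIFF stacks.
#' @param calibration_path JSON with at least `i1_mean` (as written by
#'   [save_calibration()]), or a numeric I1 value.
#' @param out_dir output directory (created if needed).
#' @param config_path optional YAML config (see [read_run_config()]).
#' @param overlay also write the RGB overlay stack (default TRUE).
#' @return the `analysis_report`, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(membrane_path, particles_path, calibration_path,
                         out_dir, config_path = NULL, overlay = TRUE) {
  config <- read_run_config(config_path)
  vs_override <- config$io$voxel_size_um
  membrane <- with_stage("io", read_stack(membrane_path, "membrane", vs_override))
  particles <- with_stage("io", read_stack(particles_path, "particles", vs_override))
  cal <- if (is.numeric(calibration_path)) calibration_path
         else with_stage("io", load_calibration(calibration_path))
  res <- quantify_cell(membrane, particles, cal, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- as_analysis_report(res, provenance = list(
    membrane_path = membrane_path, particles_path = particles_path,
    calibration_path = if (is.character(calibration_path)) calibration_path else NA,
    config_hash = config$config_hash))
  write_report(report, file.path(out_dir, "cell"))
  if (overlay) {
    cols <- config$io$overlay_colors
    if (is.null(cols))
      cols <- list(membrane = "cyan", intracellular = "red",
                   membrane_assoc = "yellow", extracellular = "gray")
    write_overlay(membrane, res$detection, res$regions,
                  file.path(out_dir, "overlay.tif"), colors = cols)
  }
  invisible(report)
}

#' Save / load a calibration result as JSON
#'
#' @param cal a `calibration_result`.
#' @param path JSON path.
#' @export
save_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_result"))
  jsonlite::write_json(
    list(i1_mean = cal$i1_mean, i1_sd = cal$i1_sd,
         n_spots_used = cal$n_spots_used,
         n_spots_rejected = cal$n_spots_rejected, fit_ok = cal$fit_ok,
         voxel_size = as.numeric(cal$voxel_size)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$i1_mean)) stop("not a calibration file (no i1_mean): ", path)
  structure(list(i1_mean = j$i1_mean, i1_sd = j$i1_sd %||% 0,
                 n_spots_used = j$n_spots_used %||% NA_integer_,
                 n_spots_rejected = j$n_spots_rejected %||% NA_integer_,
                 fit_ok = isTRUE(j$fit_ok), rejected = numeric(0),
                 voxel_size = j$voxel_size),
            class = "calibration_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
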