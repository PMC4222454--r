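#' Assign each detected object to a subcellular region
#'
#' An object is labelled by the region — intracellular, membrane (shell) or
#' extracellular — containing the voxel nearest its intensity-weighted
#' centroid. Centroid-based assignment is appropriate because detected
#' objects are diffraction-limited and near-pointlike relative to the 1.4 µm
#' membrane shell; border ambiguity is absorbed by the shell itself, which is
#' the transition region's purpose.
#'
#' @param detection a `detected_objects` result.
#' @param regions a `cell_regions` from [build_regions()]; must share the
#'   grid geometry of the detection.
#' @return the `detected_objects` with `region_label` filled
#'   (`"intracellular"`, `"membrane"` or `"extracellular"`).
#' @export
classify_objects <- function(detection, regions) {
  stopifnot(inherits(detection, "detected_objects"), inherits(regions, "cell_regions"))
  if (!same_geometry(detection$dim, detection$voxel_size,
                     dim(regions$cell_mask), regions$voxel_size))
    stop("geometry mismatch: detection grid and cell regions differ in shape or voxel size")
  obj <- detection$objects
  if (nrow(obj) > 0) {
    vs <- detection$voxel_size
    d <- detection$dim
    iz <- pmin(pmax(round(obj$z_um / vs[1]) + 1, 1), d[1])
    iy <- pmin(pmax(round(obj$y_um / vs[2]) + 1, 1), d[2])
    ix <- pmin(pmax(round(obj$x_um / vs[3]) + 1, 1), d[3])
    lin <- cbind(iz, iy, ix)
    lab <- rep("membrane", nrow(obj))
    lab[regions$intracellular[lin]] <- "intracellular"
    lab[regions$extracellular[lin]] <- "extracellular"
    obj$region_label <- lab
  }
  detection$objects <- obj
  detection
}

#' Convert an object's integrated intensity to an absolute particle count
#'
#' The counting rule of the method: the number of particles in an object is
#' its integrated intensity divided by the single-particle intensity I1,
#' rounded to the nearest integer (half up). The rule rests on intensity
#' additivity — self-quenching of the dye inside agglomerates is assumed
#' negligible, so a k-particle agglomerate is k times as bright as one
#' particle. A detected object represents at least one particle, so counts
#' are clamped at 1.
#'
#' @param integrated_intensity numeric vector of object intensities.
#' @param cal a `calibration_result` (must have `fit_ok = TRUE`), or a single
#'   positive number taken directly as I1.
#' @return integer vector of particle counts (>= 1).
#' @examples
#' count_particles(c(48090, 96180, 0.4 * 48090), cal = 48090)  # 1, 2, 1
#' @export
count_particles <- function(integrated_intensity, cal) {
  i1 <- if (inherits(cal, "calibration_result")) {
    if (!isTRUE(cal$fit_ok))
      stop("calibration fit is not usable (fit_ok = FALSE)")
    cal$i1_mean
  } else as.numeric(cal)[1]
  if (!is.finite(i1) || i1 <= 0) stop("single-particle intensity I1 must be positive")
  stopifnot(all(integrated_intensity > 0))
  pmax(1L, as.integer(floor(integrated_intensity / i1 + 0.5)))
}

#' Classify, count and total the particles of one cell
#'
#' Combines [classify_objects()] and [count_particles()] and sums the
#' per-object counts into per-region totals — the per-cell quantities
#' (intracellular, membrane-associated, extracellular particle numbers) that
#' form the unit of analysis in uptake experiments.
#'
#' @param detection a `detected_objects` result.
#' @param regions a `cell_regions`.
#' @param cal a `calibration_result` or a plain I1 value.
#' @return a `cell_uptake_result`: `objects` (data frame with `region_label`
#'   and `n_particles` filled), `totals` (named vector `n_intracellular`,
#'   `n_membrane`, `n_extracellular`, `n_total`), `calibration`.
#' @export
summarize_cell <- function(detection, regions, cal) {
  detection <- classify_objects(detection, regions)
  obj <- detection$objects
  if (nrow(obj) > 0)
    obj$n_particles <- count_particles(obj$integrated_intensity, cal)
  tot_for <- function(lbl) sum(obj$n_particles[obj$region_label == lbl])
  totals <- c(n_intracellular = tot_for("intracellular"),
              n_membrane = tot_for("membrane"),
              n_extracellular = tot_for("extracellular"))
  totals <- c(totals, n_total = sum(totals))
  detection$objects <- obj
  structure(list(objects = obj, totals = totals, calibration = cal,
                 detection = detection, regions_shell_width_um = regions$shell_width_um),
            class = "cell_uptake_result")
}

#' @export
print.cell_uptake_result <- function(x, ...) {
  cat("<cell_uptake_result>\n")
  cat(sprintf("  %d object(s): %d intracellular / %d membrane-associated / %d extracellular particles (total %d)\n",
              nrow(x$objects), x$totals["n_intracellular"], x$totals["n_membrane"],
              x$totals["n_extracellular"], x$totals["n_total"]))
  invisible(x)
}

#' Package a cell's result as a serialisable analysis report
#'
#' @param result a `cell_uptake_result`.
#' @param provenance named list recorded verbatim (input paths, config hash,
#'   calibration I1, ...).
#' @return an `analysis_report` with `per_object` (data frame), `per_cell`
#'   (named counts) and `provenance`; its totals always satisfy
#'   `n_total == n_intracellular + n_membrane + n_extracellular`.
#' @export
as_analysis_report <- function(result, provenance = list()) {
  stopifnot(inherits(result, "cell_uptake_result"))
  i1 <- if (inherits(result$calibration, "calibration_result"))
    result$calibration$i1_mean else as.numeric(result$calibration)[1]
  provenance$calibration_i1 <- i1
  as_analysis_report_raw(result$objects[, c("object_id", "x_um", "y_um", "z_um",
                                            "region_label", "integrated_intensity",
                                            "n_particles")],
                         result$totals, provenance)
}

as_analysis_report_raw <- function(per_object, per_cell, provenance) {
  per_cell <- per_cell[c("n_intracellular", "n_membrane", "n_extracellular", "n_total")]
  if (per_cell[["n_total"]] !=
      per_cell[["n_intracellular"]] + per_cell[["n_membrane"]] + per_cell[["n_extracellular"]])
    stop("report totals are inconsistent")
  for (lbl in c("intracellular", "membrane", "extracellular")) {
    want <- sum(per_object$n_particles[per_object$region_label == lbl])
    have <- per_cell[[paste0("n_", lbl)]]
    if (want != have)
      stop("per-cell count for ", lbl, " (", have,
           ") does not match the per-object sum (", want, ")")
  }
  structure(list(per_object = per_object, per_cell = per_cell,
                 provenance = provenance),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  objects: %d; particles: %d intracellular, %d membrane, %d extracellular (total %d)\n",
              nrow(x$per_object), x$per_cell[["n_intracellular"]],
              x$per_cell[["n_membrane"]], x$per_cell[["n_extracellular"]],
              x$per_cell[["n_total"]]))
  invisible(x)
}
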