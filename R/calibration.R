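#' Fit the single-particle intensity from a set of spot intensities
#'
#' The integrated intensities of isolated calibration spots are modelled as a
#' Gaussian around the single-particle intensity I1. Because a deposited
#' calibration field inevitably contains some multi-particle spots (doublets
#' land at about 2 x I1, far outside the single-particle spread), the fit is
#' an iteratively trimmed maximum-likelihood Gaussian: fit mean and sd, drop
#' intensities outside `mean +/- trim_sd * sd`, refit, until the retained set
#' is stable (at most `max_iter` rounds).
#'
#' @param intensities numeric vector of integrated spot intensities.
#' @param min_spots minimum usable spot count (default 50).
#' @param trim_sd trimming threshold in fitted sd units (default 2.5 — for
#'   spots with ~10% intensity spread a doublet sits ~10 sd from the mean, so
#'   2.5 separates the populations cleanly).
#' @param max_iter maximum trimming rounds (default 10).
#' @return a `calibration_result`: `i1_mean`, `i1_sd`, `n_spots_used`,
#'   `n_spots_rejected`, `fit_ok` (`FALSE` when trimming discarded more than
#'   half the spots), `rejected` (the discarded intensities).
#' @export
fit_single_particle_intensity <- function(intensities, min_spots = 50,
                                          trim_sd = 2.5, max_iter = 10) {
  intensities <- as.numeric(intensities)
  intensities <- intensities[is.finite(intensities) & intensities > 0]
  n0 <- length(intensities)
  if (n0 < min_spots)
    stop("insufficient calibration spots: ", n0, " found, ", min_spots, " required")
  keep <- intensities
  for (it in seq_len(max_iter)) {
    m <- mean(keep)
    s <- stats::sd(keep)
    if (!is.finite(s) || s == 0) break
    inside <- abs(keep - m) <= trim_sd * s
    if (all(inside)) break
    keep <- keep[inside]
    if (length(keep) < 2) break
  }
  m <- mean(keep)
  s <- if (length(keep) > 1) stats::sd(keep) else 0
  structure(list(i1_mean = m, i1_sd = s,
                 n_spots_used = length(keep),
                 n_spots_rejected = n0 - length(keep),
                 fit_ok = length(keep) >= n0 / 2,
                 rejected = setdiff(intensities, keep)),
            class = "calibration_result")
}

#' Measure the single-particle intensity I1 from calibration stacks
#'
#' Runs the spot-detection pipeline ([subtract_background()] +
#' [detect_objects()]) on each calibration stack — particles deposited and
#' spread on a coverslip, imaged with the same settings as the cell
#' experiments — pools the integrated spot intensities and fits the
#' single-particle intensity with [fit_single_particle_intensity()].
#'
#' All calibration stacks must share one voxel geometry; a mismatch with
#' `reference_voxel_size` (e.g. the cell stack's) draws a warning, since a
#' calibration taken under different imaging parameters does not transfer.
#'
#' @param stacks a [voxel_grid()] or list of them.
#' @param det a [detection_params()] — use the same settings as for the cell
#'   stacks so the flux capture is identical.
#' @param min_spots,trim_sd,max_iter see [fit_single_particle_intensity()].
#' @param reference_voxel_size optional `c(dz, dy, dx)` to check against.
#' @return a `calibration_result`.
#' @export
calibrate_single_particle <- function(stacks, det = detection_params(),
                                      min_spots = 50, trim_sd = 2.5,
                                      max_iter = 10,
                                      reference_voxel_size = NULL) {
  if (inherits(stacks, "voxel_grid")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1, all(vapply(stacks, inherits, TRUE, "voxel_grid")))
  vs0 <- stacks[[1]]$voxel_size
  for (s in stacks)
    if (!all(abs(s$voxel_size - vs0) <= 1e-9))
      stop("calibration stacks have inconsistent voxel sizes")
  if (!is.null(reference_voxel_size) &&
      !all(abs(vs0 - reference_voxel_size) <= 1e-9 * pmax(vs0, reference_voxel_size)))
    warning("calibration voxel size c(", paste(signif(vs0, 4), collapse = ", "),
            ") differs from the cell stacks c(",
            paste(signif(reference_voxel_size, 4), collapse = ", "),
            "); calibration should use the same imaging parameters")
  ints <- unlist(lapply(stacks, function(s) {
    sub <- subtract_background(s, det)
    detect_objects(sub, det)$objects$integrated_intensity
  }))
  res <- fit_single_particle_intensity(ints, min_spots = min_spots,
                                       trim_sd = trim_sd, max_iter = max_iter)
  res$voxel_size <- vs0
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  I1 = %.6g +/- %.4g (Gaussian mean +/- sd, raw pixel intensities)\n",
              x$i1_mean, x$i1_sd))
  cat(sprintf("  spots used: %d, rejected as multi-particle/outlier: %d\n",
              x$n_spots_used, x$n_spots_rejected))
  if (!x$fit_ok)
    cat("  WARNING: trimming removed more than half the spots; fit_ok = FALSE\n")
  invisible(x)
}

#' @export
summary.calibration_result <- function(object, ...) {
  n <- object$n_spots_used
  se <- if (n > 0) object$i1_sd / sqrt(n) else NA_real_
  out <- c(i1_mean = object$i1_mean, i1_sd = object$i1_sd, i1_se = se,
           n_used = n, n_rejected = object$n_spots_rejected,
           fit_ok = as.numeric(object$fit_ok))
  class(out) <- "summary.calibration_result"
  out
}

#' @export
print.summary.calibration_result <- function(x, ...) {
  cat(sprintf("Single-particle intensity I1: %.6g (sd %.4g, se %.4g; n = %d, rejected %d)\n",
              x["i1_mean"], x["i1_sd"], x["i1_se"], x["n_used"], x["n_rejected"]))
  invisible(x)
}

#' Plot the calibration intensity histogram with the fitted Gaussian
#' @param x a `calibration_result`.
#' @param intensities optionally, the raw spot intensities to histogram.
#' @param ... passed to [graphics::hist()].
#' @export
plot.calibration_result <- function(x, intensities = NULL, ...) {
  if (is.null(intensities))
    stop("supply the raw spot `intensities` used for the fit")
  h <- graphics::hist(intensities, breaks = 30, freq = FALSE,
                      main = "Single-particle intensity calibration",
                      xlab = "integrated spot intensity (pixel intensities)", ...)
  xs <- seq(min(intensities), max(intensities), length.out = 300)
  graphics::lines(xs, stats::dnorm(xs, x$i1_mean, x$i1_sd), col = "red", lwd = 2)
  graphics::abline(v = x$i1_mean, lty = 2)
  invisible(h)
}
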