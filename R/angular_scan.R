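#' Goniometer angular scan
#'
#' Container for a measured angular scattering profile: detected power
#' (arbitrary units) versus polar angle \eqn{\theta} in degrees, measured
#' from the incident beam axis. The azimuthal angle is not resolved; all
#' downstream analysis assumes rotational symmetry about the beam.
#'
#' Angles must lie in \eqn{[-90, 90]} degrees and are stored strictly
#' increasing (unsorted input is sorted with a warning). Negative intensities
#' (detector noise floor) are clipped to zero with a warning.
#'
#' @param theta_deg polar angles in degrees.
#' @param intensity detected power per angle, arbitrary units.
#' @param wavelength_nm source wavelength in nm.
#' @param orientation slice orientation label, e.g. `"transverse"` or
#'   `"longitudinal"`.
#' @param condition immersion condition label, e.g. `"saline"`,
#'   `"glycerol10"`, `"glycerol60"`.
#' @return an object of class `angular_scan`.
#' @export
angular_scan <- function(theta_deg, intensity, wavelength_nm = 633,
                         orientation = NA_character_,
                         condition = NA_character_) {
  if (length(theta_deg) != length(intensity))
    top_error("`theta_deg` and `intensity` must have the same length.",
              "tendonoptics_domain_error")
  if (!all(is.finite(theta_deg)) || any(theta_deg < -90) || any(theta_deg > 90))
    top_error("Angles must be finite and within [-90, 90] degrees.",
              "tendonoptics_domain_error")
  if (!all(is.finite(intensity)))
    top_error("Intensities must be finite.", "tendonoptics_domain_error")
  if (is.unsorted(theta_deg, strictly = TRUE)) {
    if (anyDuplicated(theta_deg))
      top_error("Duplicate angles in scan.", "tendonoptics_domain_error")
    top_warn("Angles were not sorted; reordering scan by theta.")
    o <- order(theta_deg)
    theta_deg <- theta_deg[o]
    intensity <- intensity[o]
  }
  if (any(intensity < 0)) {
    top_warn(sprintf("%d negative intensities clipped to 0 (detector noise floor).",
                     sum(intensity < 0)))
    intensity <- pmax(intensity, 0)
  }
  structure(
    list(theta_deg = theta_deg, intensity = intensity,
         wavelength_nm = wavelength_nm, orientation = orientation,
         condition = condition),
    class = "angular_scan")
}

as_angular_scan <- function(x) {
  if (inherits(x, "angular_scan")) return(x)
  if (is.list(x) && all(c("theta_deg", "intensity") %in% names(x)))
    return(angular_scan(x$theta_deg, x$intensity,
                        wavelength_nm = x$wavelength_nm %||% 633,
                        orientation = x$orientation %||% NA_character_,
                        condition = x$condition %||% NA_character_))
  top_error("Cannot interpret input as an angular scan.",
            "tendonoptics_domain_error")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.angular_scan <- function(x, ...) {
  cat(sprintf("Angular scan: %d angles [%g, %g] deg, %g nm, %s / %s\n",
              length(x$theta_deg), min(x$theta_deg), max(x$theta_deg),
              x$wavelength_nm, x$orientation, x$condition))
  invisible(x)
}

#' Average a replicate group of angular scans
#'
#' Scans taken on replicate specimens are averaged point-wise on a common
#' angle grid before phase-function fitting, mirroring the usual practice of
#' fitting the averaged angular scattering distribution of a sample group.
#'
#' @param scans a list of [angular_scan()] objects sharing one angle grid.
#' @return a single [angular_scan()] with mean intensities.
#' @export
average_scans <- function(scans) {
  scans <- lapply(scans, as_angular_scan)
  if (length(scans) == 0)
    top_error("No scans to average.", "tendonoptics_domain_error")
  th <- scans[[1]]$theta_deg
  for (s in scans)
    if (length(s$theta_deg) != length(th) || any(abs(s$theta_deg - th) > 1e-9))
      top_error("Scans must share a common angle grid to be averaged.",
                "tendonoptics_domain_error")
  I <- rowMeans(sapply(scans, function(s) s$intensity))
  angular_scan(th, I,
               wavelength_nm = scans[[1]]$wavelength_nm,
               orientation = scans[[1]]$orientation,
               condition = scans[[1]]$condition)
}
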