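#' Bulk optical properties of a turbid medium
#'
#' Bundles the absorption coefficient \eqn{\mu_a}, scattering coefficient
#' \eqn{\mu_s}, anisotropy factor \eqn{g} and refractive index \eqn{n} of a
#' homogeneous medium. Either `mus` or the reduced scattering coefficient
#' `musp` may be given; the other is derived through
#' \eqn{\mu_s' = \mu_s (1 - g)}.
#'
#' @param mua absorption coefficient, mm^-1 (>= 0).
#' @param mus scattering coefficient, mm^-1 (>= 0); omit if `musp` is given.
#' @param g anisotropy factor in (-1, 1).
#' @param n refractive index (>= 1).
#' @param musp reduced scattering coefficient, mm^-1; alternative to `mus`.
#' @return an object of class `optical_properties` with fields `mua`, `mus`,
#'   `musp`, `g`, `n`.
#' @export
optical_properties <- function(mua, mus = NULL, g = 0, n = 1.40, musp = NULL) {
  if (is.null(mus) && is.null(musp))
    top_error("Provide `mus` or `musp`.", "tendonoptics_domain_error")
  if (!is.finite(g) || abs(g) >= 1)
    top_error("`g` must lie strictly in (-1, 1).", "tendonoptics_domain_error")
  if (is.null(mus)) mus <- musp / (1 - g)
  if (!is.finite(mua) || mua < 0 || !is.finite(mus) || mus < 0)
    top_error("`mua` and `mus` must be finite and >= 0.",
              "tendonoptics_domain_error")
  if (!is.finite(n) || n < 1)
    top_error("`n` must be >= 1.", "tendonoptics_domain_error")
  structure(list(mua = mua, mus = mus, musp = mus * (1 - g), g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties: mua = %g, mus = %g, musp = %g mm^-1; g = %g; n = %g\n",
              x$mua, x$mus, x$musp, x$g, x$n))
  invisible(x)
}

#' Slab geometry for reflectance/transmittance simulations
#'
#' A laterally infinite slab of given thickness, bounded above and below by
#' ambient media of the given refractive indices. Index mismatches produce
#' Fresnel reflection and refraction at the faces; the specular reflection of
#' the incident beam is excluded from the diffuse reflectance tally (as in an
#' integrating-sphere configuration where specular light exits the sphere).
#'
#' @param thickness slab thickness, mm (> 0).
#' @param n_above,n_below ambient refractive indices (>= 1).
#' @return an object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness, n_above = 1.0, n_below = 1.0) {
  if (!is.finite(thickness) || thickness <= 0)
    top_error("`thickness` must be positive.", "tendonoptics_domain_error")
  if (n_above < 1 || n_below < 1)
    top_error("Ambient refractive indices must be >= 1.",
              "tendonoptics_domain_error")
  structure(list(thickness = thickness, n_above = n_above, n_below = n_below),
            class = "slab_geometry")
}

#' Sample the Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of \eqn{\cos\theta} for the HG phase function. With
#' `u` supplied the mapping is deterministic (useful for verification); with
#' `n` supplied, `n` pseudo-random draws are generated from the given seed,
#' independent of R's global RNG state.
#'
#' @param g anisotropy factor in (-1, 1).
#' @param u optional uniform variates in \[0, 1).
#' @param n optional number of seeded draws.
#' @param seed integer seed used when `n` is given.
#' @return deflection cosines in \[-1, 1\].
#' @export
sample_hg_deflection <- function(g, u = NULL, n = NULL, seed = 1) {
  if (!is.finite(g) || abs(g) >= 1)
    top_error("`g` must lie strictly in (-1, 1).", "tendonoptics_domain_error")
  if (!is.null(u)) {
    if (any(u < 0) || any(u >= 1))
      top_error("`u` must lie in [0, 1).", "tendonoptics_domain_error")
    return(.hg_cost_from_u(g, as.numeric(u)))
  }
  if (is.null(n))
    top_error("Provide `u` or `n`.", "tendonoptics_domain_error")
  .mc_sample_hg(g, as.integer(n), as.numeric(seed))
}

#' Monte-Carlo reflectance and transmittance of a slab
#'
#' Runs weighted-packet Monte-Carlo photon transport for a pencil beam
#' normally incident on a laterally infinite slab and tallies the diffuse
#' reflectance `Rd` (specular component excluded), total transmittance `Tt`,
#' absorbed fraction `A` and specular reflectance `Rsp`. The transport rules
#' are the standard ones: exponential steps with mean \eqn{1/\mu_t},
#' per-interaction absorption \eqn{w \mu_a/\mu_t}, HG deflection with
#' uniform azimuth, Fresnel reflection at the faces, and Russian roulette
#' below weight 1e-4 with survival probability 0.1. Results are
#' deterministic for a fixed `(seed, n_photons)` pair.
#'
#' @param props an [optical_properties()] object.
#' @param geom a [slab_geometry()] object.
#' @param n_photons number of photon packets (>= 1000).
#' @param seed integer seed for the simulation's own RNG.
#' @return a list with `Rd`, `Tt`, `A`, `Rsp`; `Rd + Tt + A + Rsp = 1` up to
#'   the roulette tolerance.
#' @export
run_slab <- function(props, geom, n_photons = 1e5, seed = 1) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "slab_geometry"))
  if (n_photons < 1e3)
    top_error("`n_photons` must be at least 1000.", "tendonoptics_domain_error")
  out <- .mc_slab(props$mua, props$mus, props$g, geom$thickness,
                  props$n, geom$n_above, geom$n_below,
                  as.numeric(n_photons), as.numeric(seed))
  as.list(out)
}

#' Volume geometry for fluence simulations
#'
#' A rectangular voxelized volume illuminated by a flat-top disc beam (an
#' optical fiber tip in contact with the entry face), centred on the
#' \eqn{z = 0} face and directed along \eqn{+z}. Photon packets crossing any
#' face leave the volume and are tallied per face. With
#' `boundary = "fresnel"` the tissue/ambient refractive-index step is
#' honoured at every face: packets within the total-internal-reflection cone
#' are returned to the medium, the rest escape, which reproduces the light
#' guiding a bare tissue surface exhibits. With `boundary = "matched"` every
#' face transmits all incident weight (index-matched surroundings).
#'
#' @param dims volume dimensions `c(x, y, z)` in mm; multiples of `voxel`.
#' @param voxel cubic voxel edge length, mm (<= 1 and small enough to
#'   resolve the beam).
#' @param beam_diameter source disc diameter, mm.
#' @param boundary `"fresnel"` or `"matched"` (applies to all faces).
#' @param n_ambient ambient refractive index used by `"fresnel"` boundaries.
#' @return an object of class `volume_geometry`.
#' @export
volume_geometry <- function(dims = c(13.8, 13.8, 50), voxel = 0.2,
                            beam_diameter = 0.2,
                            boundary = c("fresnel", "matched"),
                            n_ambient = 1.0) {
  boundary <- match.arg(boundary)
  if (length(dims) != 3 || any(!is.finite(dims)) || any(dims <= 0))
    top_error("`dims` must be three positive lengths (mm).",
              "tendonoptics_domain_error")
  if (voxel <= 0 || voxel > 1)
    top_error("`voxel` must be in (0, 1] mm.", "tendonoptics_domain_error")
  nvox <- dims / voxel
  if (any(abs(nvox - round(nvox)) > 1e-6))
    top_error("`dims` must be positive multiples of `voxel`.",
              "tendonoptics_domain_error")
  if (beam_diameter < 0 || beam_diameter > min(dims[1:2]))
    top_error("`beam_diameter` must fit inside the entry face.",
              "tendonoptics_domain_error")
  structure(list(dims = dims, voxel = voxel, beam_diameter = beam_diameter,
                 boundary = boundary, n_ambient = n_ambient),
            class = "volume_geometry")
}

#' Monte-Carlo fluence map of a voxelized volume
#'
#' Transports photon packets through the volume and accumulates the fluence
#' \eqn{\phi} in each voxel with a track-length estimator
#' (weight x path length / voxel volume, per launched packet, mm^-2). The
#' weight escaping through the far face within the detector area is reported
#' as `transmitted_fraction`. An on-axis depth profile \eqn{\phi(z)} and its
#' fitted exponential attenuation slope \eqn{\mu_{eff}} are attached via
#' [depth_profile()] and [fit_mueff()].
#'
#' @param props an [optical_properties()] object.
#' @param geom a [volume_geometry()] object.
#' @param n_photons number of photon packets.
#' @param seed integer seed.
#' @param detector_radius radius (mm) of a centred circular detector on the
#'   far face; `0` (default) uses the entire face.
#' @param profile_radius averaging radius (mm) around the beam axis for the
#'   depth profile; defaults to 0.5 mm.
#' @param mueff_window depth window (mm) for the attenuation-slope fit.
#' @return an object of class `fluence_map`: `phi` (3-D array, mm^-2),
#'   `x`, `y`, `z` voxel-centre coordinates (mm), `escaped` (per-face
#'   fractions), `absorbed`, `transmitted_fraction`, `Rsp`, `profile`
#'   (data frame `z_mm`, `phi`), `mueff` and `mueff_window`.
#' @export
score_fluence <- function(props, geom, n_photons = 1e5, seed = 1,
                          detector_radius = 0, profile_radius = 0.5,
                          mueff_window = c(5, 45)) {
  stopifnot(inherits(props, "optical_properties"),
            inherits(geom, "volume_geometry"))
  res <- .mc_volume(props$mua, props$mus, props$g,
                    props$n, geom$n_ambient,
                    geom$dims[1], geom$dims[2], geom$dims[3], geom$voxel,
                    geom$beam_diameter, geom$boundary == "fresnel",
                    as.numeric(detector_radius),
                    as.numeric(n_photons), as.numeric(seed))
  d <- dim(res$phi)
  map <- structure(
    list(phi = res$phi,
         x = (seq_len(d[1]) - 0.5) * geom$voxel,
         y = (seq_len(d[2]) - 0.5) * geom$voxel,
         z = (seq_len(d[3]) - 0.5) * geom$voxel,
         voxel = geom$voxel, dims = geom$dims,
         escaped = as.list(res$escaped),
         absorbed = res$absorbed,
         transmitted_fraction = res$transmitted,
         Rsp = res$Rsp,
         props = props, geom = geom,
         n_photons = n_photons, seed = seed),
    class = "fluence_map")
  map$profile <- depth_profile(map, radius = profile_radius)
  fit <- fit_mueff(map$profile$z_mm, map$profile$phi, window = mueff_window)
  map$mueff <- fit$mueff
  map$mueff_window <- fit$window
  map
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("Fluence map: %s voxels (%g mm), transmitted fraction %.4g\n",
              paste(dim(x$phi), collapse = " x "), x$voxel,
              x$transmitted_fraction))
  if (is.finite(x$mueff))
    cat(sprintf("  fitted mueff = %.4g mm^-1 over z in [%g, %g] mm\n",
                x$mueff, x$mueff_window[1], x$mueff_window[2]))
  invisible(x)
}

#' On-axis depth profile of a fluence map
#'
#' Mean fluence versus depth over the voxel columns whose centres lie within
#' `radius` of the beam axis (x = y = centre). `radius = 0` uses the single
#' on-axis column; a small positive radius trades a little lateral blurring
#' for much lower Monte-Carlo variance.
#'
#' @param map a `fluence_map`.
#' @param radius averaging radius in mm.
#' @return a data frame with columns `z_mm` and `phi`.
#' @export
depth_profile <- function(map, radius = 0.5) {
  stopifnot(inherits(map, "fluence_map"))
  cx <- map$dims[1] / 2
  cy <- map$dims[2] / 2
  r2 <- (map$x - cx)^2
  keep_x <- which(outer(r2, (map$y - cy)^2, "+") <= max(radius, map$voxel / 2)^2,
                  arr.ind = TRUE)
  if (nrow(keep_x) == 0) { # fall back to nearest column
    ix <- which.min(abs(map$x - cx)); iy <- which.min(abs(map$y - cy))
    keep_x <- cbind(ix, iy)
  }
  phi_z <- vapply(seq_along(map$z), function(k) {
    mean(map$phi[cbind(keep_x[, 1], keep_x[, 2], k)])
  }, numeric(1))
  data.frame(z_mm = map$z, phi = phi_z)
}

#' Fit the effective attenuation slope of a depth profile
#'
#' Linear regression of \eqn{\ln \phi(z)} on depth over a given window; the
#' negative slope is the effective attenuation coefficient \eqn{\mu_{eff}}
#' (mm^-1). Zero or non-finite fluence bins are dropped. The window matters
#' for narrow illuminated volumes, where the profile is not a single
#' exponential near the source; the default \[5, 45\] mm skips the
#' near-source transient.
#'
#' @param z depths, mm.
#' @param phi fluence values (> 0 where used).
#' @param window `c(zmin, zmax)` fitting window in mm.
#' @return a list with `mueff` (mm^-1), `intercept`, `window`, `n_points`.
#' @export
fit_mueff <- function(z, phi, window = c(5, 45)) {
  keep <- is.finite(phi) & phi > 0 & z >= window[1] & z <= window[2]
  if (sum(keep) < 3)
    return(list(mueff = NA_real_, intercept = NA_real_,
                window = window, n_points = sum(keep)))
  fit <- lm(log(phi[keep]) ~ z[keep])
  list(mueff = -unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       window = window, n_points = sum(keep))
}
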