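# Synthetic-instrument generators: goniometer scans and integrating-sphere
# spectra drawn from known ground truth, so the whole pipeline is testable
# without any measured data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic goniometer scan
#'
#' Parameters of the two-lobe HG model plus an instrument noise description:
#' multiplicative Gaussian noise of relative standard deviation `noise_rel`
#' and an additive stray-light floor expressed as a fraction of the peak
#' model intensity. The defaults (2 percent multiplicative noise, floor at
#' 0.2 percent of peak) are of the order suggested by the specimen-to-specimen
#' variability of goniometer measurements on thin tissue slices.
#'
#' @param K1,g1,K2,g2 two-lobe model parameters (see [double_hg_fit()]).
#' @param noise_rel relative s.d. of multiplicative noise (>= 0).
#' @param floor_frac stray-light floor as a fraction of the peak intensity.
#' @param theta_deg angle grid in degrees.
#' @return a list of class `goniometer_truth`.
#' @export
goniometer_truth <- function(K1 = 1.0, g1 = 0.94, K2 = 0.5, g2 = 0.65,
                             noise_rel = 0.02, floor_frac = 0.002,
                             theta_deg = seq(-50, 50, by = 1)) {
  if (noise_rel < 0 || floor_frac < 0)
    top_error("Noise parameters must be >= 0.", "tendonoptics_domain_error")
  structure(list(K1 = K1, g1 = g1, K2 = K2, g2 = g2,
                 noise_rel = noise_rel, floor_frac = floor_frac,
                 theta_deg = theta_deg),
            class = "goniometer_truth")
}

#' Generate a synthetic goniometer scan
#'
#' Evaluates the two-lobe model on the truth's angle grid and applies
#' instrument noise:
#' `intensity = model * (1 + eps) + floor`, with `eps` seeded Gaussian of
#' s.d. `noise_rel` and `floor = floor_frac * max(model)`. Deterministic for
#' a fixed `(truth, seed)` pair; R's global RNG state is left untouched.
#'
#' @param truth a [goniometer_truth()].
#' @param seed integer seed.
#' @param wavelength_nm,orientation,condition metadata for the scan.
#' @return an [angular_scan()].
#' @export
gen_goniometer_scan <- function(truth, seed = 1, wavelength_nm = 633,
                                orientation = NA_character_,
                                condition = NA_character_) {
  stopifnot(inherits(truth, "goniometer_truth"))
  fit <- double_hg_fit(truth$K1, truth$g1, truth$K2, truth$g2)
  th <- truth$theta_deg * pi / 180
  model <- double_hg_model(abs(th), fit)
  eps <- if (truth$noise_rel > 0)
    with_seed(seed, rnorm(length(th), 0, truth$noise_rel)) else 0
  floor_au <- truth$floor_frac * max(model)
  intensity <- pmax(model * (1 + eps) + floor_au, 0)
  angular_scan(truth$theta_deg, intensity, wavelength_nm = wavelength_nm,
               orientation = orientation, condition = condition)
}

#' Ground truth for synthetic Rd/Tt spectra
#'
#' Forward-model parameters for generating integrating-sphere spectra:
#' water fraction `Wt`, power-law scattering `(a, b)`, slab anisotropy `g`
#' and thickness, plus the experimental loss factor `K_true` (measured
#' spectra are *divided* by `K_true`, emulating setup losses that the
#' inversion must undo) and relative detector noise.
#'
#' @param Wt water volume fraction in \[0, 1\].
#' @param a,b power-law scattering parameters.
#' @param K_true loss factor (> 0); 1 means a lossless setup.
#' @param g slab anisotropy; `n_tissue` refractive index.
#' @param thickness_mm slab thickness, mm.
#' @param wavelength_nm wavelength grid, nm (within the water table).
#' @param n_photons photon packets per wavelength.
#' @param noise_rel relative s.d. of detector noise on Rd and Tt.
#' @return a list of class `spectra_truth`.
#' @export
spectra_truth <- function(Wt = 0.65, a = 1.54, b = 2.10, K_true = 1.22,
                          g = 0.70, thickness_mm = 1.5,
                          wavelength_nm = seq(450, 1250, length.out = 25),
                          n_photons = 1e4, noise_rel = 0.01,
                          n_tissue = 1.40) {
  if (Wt < 0 || Wt > 1) top_error("`Wt` must lie in [0, 1].",
                                  "tendonoptics_domain_error")
  if (K_true <= 0) top_error("`K_true` must be positive.",
                             "tendonoptics_domain_error")
  if (a <= 0) top_error("`a` must be positive.", "tendonoptics_domain_error")
  structure(list(Wt = Wt, a = a, b = b, K_true = K_true, g = g,
                 thickness_mm = thickness_mm, wavelength_nm = wavelength_nm,
                 n_photons = n_photons, noise_rel = noise_rel,
                 n_tissue = n_tissue),
            class = "spectra_truth")
}

#' Generate synthetic Rd/Tt spectra by forward Monte Carlo
#'
#' For each wavelength, computes \eqn{\mu_a} and \eqn{\mu_s'} from the truth
#' parameters, runs the slab Monte Carlo, divides both channels by `K_true`
#' (undetected losses shrink what the instrument reports) and applies seeded
#' relative Gaussian noise.
#'
#' @param truth a [spectra_truth()].
#' @param seed integer seed (drives both the MC streams and the noise).
#' @param orientation,condition metadata labels.
#' @return a [spectrum_measurement()].
#' @export
gen_spectra <- function(truth, seed = 1, orientation = NA_character_,
                        condition = NA_character_) {
  stopifnot(inherits(truth, "spectra_truth"))
  lam <- truth$wavelength_nm
  geom <- slab_geometry(truth$thickness_mm)
  mua <- mua_model(lam, truth$Wt)
  musp <- musp_model(lam, truth$a, truth$b)
  Rd <- Tt <- numeric(length(lam))
  for (i in seq_along(lam)) {
    props <- optical_properties(mua = mua[i], musp = musp[i], g = truth$g,
                                n = truth$n_tissue)
    out <- run_slab(props, geom, n_photons = truth$n_photons,
                    seed = seed + i - 1)
    Rd[i] <- out$Rd
    Tt[i] <- out$Tt
  }
  if (truth$noise_rel > 0) {
    eps <- with_seed(seed + 100003L,
                     rnorm(2 * length(lam), 0, truth$noise_rel))
    Rd <- Rd * (1 + eps[seq_along(lam)])
    Tt <- Tt * (1 + eps[length(lam) + seq_along(lam)])
  }
  spectrum_measurement(lam, pmax(Rd, 0) / truth$K_true,
                       pmax(Tt, 0) / truth$K_true,
                       thickness_mm = truth$thickness_mm,
                       orientation = orientation, condition = condition)
}

# Preset truths: orientation/condition pairs qualitatively mirroring
# saline-soaked and glycerol-cleared tendon (higher g, lower a after
# clearing). These are presets for generating test data, not claims about
# any particular specimen.
fixture_presets <- function() {
  list(
    list(orientation = "transverse", condition = "saline",
         gonio = goniometer_truth(K1 = 1.0, g1 = 0.90, K2 = 0.55, g2 = 0.45),
         spectra = spectra_truth(a = 1.54, b = 2.10, K_true = 1.22, g = 0.70)),
    list(orientation = "longitudinal", condition = "saline",
         gonio = goniometer_truth(K1 = 1.2, g1 = 0.94, K2 = 0.45, g2 = 0.55),
         spectra = spectra_truth(a = 8.0, b = 2.6, K_true = 1.30, g = 0.80,
                                 n_photons = 5e3)),
    list(orientation = "transverse", condition = "glycerol10",
         gonio = goniometer_truth(K1 = 1.1, g1 = 0.93, K2 = 0.35, g2 = 0.55),
         spectra = spectra_truth(a = 1.01, b = 2.20, K_true = 1.18, g = 0.91)),
    list(orientation = "longitudinal", condition = "glycerol10",
         gonio = goniometer_truth(K1 = 1.25, g1 = 0.95, K2 = 0.30, g2 = 0.60),
         spectra = spectra_truth(a = 6.0, b = 2.8, K_true = 1.35, g = 0.95,
                                 n_photons = 5e3)))
}

#' Write a deterministic bundle of synthetic fixtures
#'
#' Generates paired transverse/longitudinal goniometer scans and Rd/Tt
#' spectra for saline-like and glycerol-like presets, writes them as CSV
#' files plus a JSON manifest mapping every file to its ground-truth
#' parameters and seed. Byte-identical for identical seeds.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return the manifest (a list), invisibly; files are written under `dir`.
#' @export
gen_fixture_suite <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, files = list())
  presets <- fixture_presets()
  for (i in seq_along(presets)) {
    p <- presets[[i]]
    tag <- paste0(p$orientation, "_", p$condition)
    scan_seed <- seed + 10 * i
    spec_seed <- seed + 10 * i + 5
    scan <- gen_goniometer_scan(p$gonio, seed = scan_seed,
                                orientation = p$orientation,
                                condition = p$condition)
    spec <- gen_spectra(p$spectra, seed = spec_seed,
                        orientation = p$orientation, condition = p$condition)
    scan_file <- file.path(dir, paste0("scan_", tag, ".csv"))
    spec_file <- file.path(dir, paste0("spectra_", tag, ".csv"))
    write_angular_csv(scan, scan_file)
    write_spectra_csv(spec, spec_file)
    manifest$files[[basename(scan_file)]] <- list(
      type = "angular_scan", seed = scan_seed,
      truth = unclass(p$gonio)[c("K1", "g1", "K2", "g2",
                                 "noise_rel", "floor_frac")])
    manifest$files[[basename(spec_file)]] <- list(
      type = "spectrum", seed = spec_seed,
      truth = unclass(p$spectra)[c("Wt", "a", "b", "K_true", "g",
                                   "thickness_mm", "n_photons", "noise_rel")])
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
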