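#' Integrating-sphere spectrum measurement
#'
#' Wavelength-resolved diffuse reflectance and total transmittance of a slab
#' sample, as fractions of the incident power. Wavelengths must be ascending
#' within 250-2500 nm; raw fractions above 1.1 are rejected as unphysical
#' (values slightly above 1 can occur before loss scaling is applied).
#'
#' @param wavelength_nm ascending wavelength grid, nm.
#' @param Rd diffuse reflectance fractions.
#' @param Tt total transmittance fractions.
#' @param thickness_mm sample thickness, mm.
#' @param orientation,condition optional labels.
#' @return an object of class `spectrum_measurement`.
#' @export
spectrum_measurement <- function(wavelength_nm, Rd, Tt, thickness_mm,
                                 orientation = NA_character_,
                                 condition = NA_character_) {
  n <- length(wavelength_nm)
  if (length(Rd) != n || length(Tt) != n)
    top_error("`Rd` and `Tt` must match the wavelength grid length.",
              "tendonoptics_domain_error")
  if (is.unsorted(wavelength_nm, strictly = TRUE) ||
      any(wavelength_nm < 250) || any(wavelength_nm > 2500))
    top_error("Wavelengths must be strictly ascending within [250, 2500] nm.",
              "tendonoptics_domain_error")
  if (any(!is.finite(Rd)) || any(!is.finite(Tt)) || any(Rd < 0) || any(Tt < 0))
    top_error("Rd and Tt must be finite and >= 0.", "tendonoptics_domain_error")
  if (any(Rd > 1.1) || any(Tt > 1.1))
    top_error("Rd or Tt exceeds the sanity bound of 1.1.",
              "tendonoptics_domain_error")
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    top_error("`thickness_mm` must be positive.", "tendonoptics_domain_error")
  structure(list(wavelength_nm = wavelength_nm, Rd = Rd, Tt = Tt,
                 thickness_mm = thickness_mm, orientation = orientation,
                 condition = condition),
            class = "spectrum_measurement")
}

#' @export
print.spectrum_measurement <- function(x, ...) {
  cat(sprintf("Spectrum: %d wavelengths [%g, %g] nm, thickness %g mm, %s / %s\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$thickness_mm, x$orientation,
              x$condition))
  invisible(x)
}

#' Model reflectance and transmittance spectra from a lookup table
#'
#' Evaluates the forward model at each wavelength: absorption from the
#' water-scaled model \eqn{\mu_a = W_t \mu_{a,water}(\lambda)}, reduced
#' scattering from the power law \eqn{\mu_s' = a (\lambda/500)^{-b}}, then
#' bilinear interpolation of the Monte-Carlo lookup table at
#' \eqn{(\mu_a, \mu_s')}. Queries falling outside the table raise a coverage
#' error naming the offending wavelength.
#'
#' @param wavelength_nm wavelengths, nm.
#' @param Wt water volume fraction.
#' @param a,b power-law reduced scattering parameters (see [musp_model()]).
#' @param lut an `optics_lut` from [build_lut()].
#' @param water water absorption table.
#' @return a list with vectors `Rd_model`, `Tt_model`, `mua`, `musp`.
#' @export
predict_rd_tt <- function(wavelength_nm, Wt, a, b, lut,
                          water = water_absorption_table()) {
  mua <- mua_model(wavelength_nm, Wt, table = water)
  musp <- musp_model(wavelength_nm, a, b)
  pred <- tryCatch(
    lut_interp(lut, mua, musp, clamp = FALSE),
    tendonoptics_lut_coverage = function(e) {
      i <- e$queries[1]
      top_error(sprintf(
        "LUT grid needs extension: query at %g nm (mua = %.3g, musp = %.3g mm^-1) is outside the table.",
        wavelength_nm[i], mua[i], musp[i]),
        "tendonoptics_lut_coverage", queries = e$queries)
    })
  list(Rd_model = pred$Rd, Tt_model = pred$Tt, mua = mua, musp = musp)
}

default_inversion_bounds <- function() {
  list(lower = c(Wt = 0, a = 1e-6, b = 0, K = 0.5),
       upper = c(Wt = 0.65, a = 100, b = 6, K = 2))
}

#' Invert Rd/Tt spectra for water content and scattering parameters
#'
#' Recovers `(Wt, a, b, K)` from measured diffuse reflectance and total
#' transmittance spectra by bounded nonlinear least squares against lookup
#' table predictions. The objective is
#' \deqn{\sum_\lambda (K R_d^{meas} - R_d^{model})^2 +
#'       (K T_t^{meas} - T_t^{model})^2,}
#' i.e. the experimental data (not the model) are scaled by the loss factor
#' `K`, which compensates setup losses such as lateral light escaping at the
#' sphere port. Scaling both channels by the same K assumes reflectance and
#' transmittance suffer proportionally equal losses, which is a documented
#' approximation rather than an exact property of sphere measurements.
#'
#' Bounds default to \eqn{W_t \in [0, 0.65]} (native tendon is roughly 62
#' percent water, so the water-scaled absorption cannot exceed that
#' fraction), \eqn{a \in (0, 100]}, \eqn{b \in [0, 6]},
#' \eqn{K \in [0.5, 2]}. Levenberg-Marquardt least squares is run from a
#' small set of deterministic starts perturbing `(a, b)`; the best residual
#' wins. During optimization, out-of-table queries are clamped to the table
#' edge; if the *final* parameters still fall outside, the table is rebuilt
#' once with expanded grids (using its recorded metadata) and the fit is
#' repeated.
#'
#' @param meas a [spectrum_measurement()].
#' @param lut an `optics_lut`; its thickness metadata must match `meas`.
#' @param bounds list with `lower` and `upper` named vectors over
#'   `(Wt, a, b, K)`.
#' @param init named start vector; default `c(Wt=0.65, a=1, b=1.5, K=1.2)`.
#' @param water water absorption table.
#' @param auto_expand rebuild the LUT once if the fitted parameters need a
#'   larger table.
#' @return an object of class `scatter_model_fit`: fitted `Wt`, `a`, `b`,
#'   `K`, `residual`, per-wavelength `mua` and `musp`, model spectra, and
#'   the LUT metadata used.
#' @export
invert_spectra <- function(meas, lut,
                           bounds = default_inversion_bounds(),
                           init = c(Wt = 0.65, a = 1.0, b = 1.5, K = 1.2),
                           water = water_absorption_table(),
                           auto_expand = TRUE) {
  stopifnot(inherits(meas, "spectrum_measurement"),
            inherits(lut, "optics_lut"))
  if (length(meas$wavelength_nm) < 10)
    top_error("At least 10 wavelengths are required for inversion.",
              "tendonoptics_domain_error")
  if (abs(lut$meta$thickness_mm - meas$thickness_mm) > 1e-9)
    top_error(sprintf(
      "LUT thickness (%g mm) does not match measurement thickness (%g mm).",
      lut$meta$thickness_mm, meas$thickness_mm),
      "tendonoptics_geometry_mismatch")

  lam <- meas$wavelength_nm
  mua_w <- water_mua(lam, table = water)

  resid_fn <- function(par, lut) {
    mua <- par[1] * mua_w
    musp <- musp_model(lam, max(par[2], 1e-9), par[3])
    pred <- lut_interp(lut, mua, musp, clamp = TRUE)
    c(par[4] * meas$Rd - pred$Rd, par[4] * meas$Tt - pred$Tt)
  }

  run_fit <- function(lut) {
    lower <- bounds$lower; upper <- bounds$upper
    # multi-starts perturb (a, b); two also move Wt off its upper bound,
    # where the bounded Levenberg-Marquardt can otherwise freeze it
    starts <- list(init,
                   replace(init, "Wt", 0.40),
                   replace(init, c("Wt", "a", "b"),
                           c(0.40, init[["a"]] * 0.2, 1.0)),
                   replace(init, c("a", "b"), c(init[["a"]] * 5, 2.5)),
                   replace(init, c("a", "b"), c(init[["a"]] * 25, 3.5)))
    best <- NULL
    for (p0 in starts) {
      p0 <- pmin(pmax(p0, lower), upper)
      res <- tryCatch(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, lut = lut,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 400, ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (is.null(res)) next
      obj <- sum(resid_fn(res$par, lut)^2)
      if (is.null(best) || obj < best$obj) best <- list(par = res$par, obj = obj)
    }
    if (is.null(best))
      top_error("Spectral inversion failed to converge from any start.",
                "tendonoptics_fit_failure")
    best
  }

  best <- run_fit(lut)
  expanded <- FALSE

  # one-shot grid expansion if the fitted optimum needs queries off-table
  need <- list(mua = best$par[1] * mua_w,
               musp = musp_model(lam, max(best$par[2], 1e-9), best$par[3]))
  off <- any(need$mua > max(lut$mua_grid)) ||
    any(need$musp > max(lut$musp_grid)) ||
    any(need$musp < min(lut$musp_grid))
  if (off && auto_expand) {
    musp_lo <- min(min(lut$musp_grid), min(need$musp) / 1.5)
    musp_hi <- max(max(lut$musp_grid), max(need$musp) * 1.5)
    mua_hi <- max(max(lut$mua_grid), max(need$mua) * 1.5)
    npts <- max(length(lut$musp_grid),
                ceiling(12 * log10(musp_hi / musp_lo)))
    lut <- build_lut(
      g = lut$meta$g,
      geom = slab_geometry(lut$meta$thickness_mm, lut$meta$n_above,
                           lut$meta$n_below),
      mua_grid = c(0, 10^seq(log10(max(min(lut$mua_grid[lut$mua_grid > 0]),
                                       1e-6)),
                             log10(mua_hi), length.out = 24)),
      musp_grid = 10^seq(log10(musp_lo), log10(musp_hi), length.out = npts),
      n_photons = lut$meta$n_photons, seed = lut$meta$seed,
      n_tissue = lut$meta$n_tissue)
    best <- run_fit(lut)
    expanded <- TRUE
  }

  par <- setNames(best$par, c("Wt", "a", "b", "K"))
  mua <- par[["Wt"]] * mua_w
  musp <- musp_model(lam, par[["a"]], par[["b"]])
  pred <- lut_interp(lut, mua, musp, clamp = TRUE)

  structure(
    list(Wt = par[["Wt"]], a = par[["a"]], b = par[["b"]], K = par[["K"]],
         residual = best$obj,
         wavelength_nm = lam, mua = mua, musp = musp,
         Rd_model = pred$Rd, Tt_model = pred$Tt,
         Rd_scaled = par[["K"]] * meas$Rd, Tt_scaled = par[["K"]] * meas$Tt,
         lut_meta = lut$meta, lut_expanded = expanded,
         orientation = meas$orientation, condition = meas$condition),
    class = "scatter_model_fit")
}

#' @export
print.scatter_model_fit <- function(x, ...) {
  cat("Scattering model fit (water-scaled mua, power-law musp)\n")
  cat(sprintf("  Wt = %.3f, a = %.4g mm^-1, b = %.3f, K = %.3f\n",
              x$Wt, x$a, x$b, x$K))
  cat(sprintf("  residual = %.4g over %d wavelengths (LUT g = %g)\n",
              x$residual, length(x$wavelength_nm), x$lut_meta$g))
  invisible(x)
}

#' Export a fitted scattering model
#'
#' Writes the fitted parameters as JSON and, optionally, the per-wavelength
#' absorption and reduced scattering spectra as CSV
#' (`wavelength_nm, mua_mm, musp_mm`).
#'
#' @param fit a `scatter_model_fit`.
#' @param json_path path for the JSON parameter report.
#' @param csv_path optional path for the spectra CSV.
#' @return `json_path`, invisibly.
#' @export
write_fit_report <- function(fit, json_path, csv_path = NULL) {
  stopifnot(inherits(fit, "scatter_model_fit"))
  jsonlite::write_json(
    list(Wt = fit$Wt, a = fit$a, b = fit$b, K = fit$K,
         residual = fit$residual, orientation = fit$orientation,
         condition = fit$condition, lut = fit$lut_meta),
    json_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(csv_path))
    write.csv(data.frame(wavelength_nm = fit$wavelength_nm,
                         mua_mm = fit$mua, musp_mm = fit$musp),
              csv_path, row.names = FALSE)
  invisible(json_path)
}
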