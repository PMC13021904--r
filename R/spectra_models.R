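#' Water absorption table (Hale-Querry compilation)
#'
#' Absorption coefficient of pure water on the native 400-1600 nm grid of the
#' classic Hale-Querry compilation of the optical constants of water. Values
#' are derived from the imaginary refractive index k via
#' \eqn{\mu_a = 4\pi k / \lambda} and returned in mm^-1. Exact digitizations
#' of this compilation differ by of order 10 percent between sources in the
#' NIR; this package treats the table as the declared reference.
#'
#' @return a data frame with columns `wavelength_nm` and `mua_mm` (mm^-1).
#' @export
water_absorption_table <- function() {
  lambda_um <- c(0.400, 0.425, 0.450, 0.475, 0.500, 0.525, 0.550, 0.575,
                 0.600, 0.625, 0.650, 0.675, 0.700, 0.725, 0.750, 0.775,
                 0.800, 0.825, 0.850, 0.875, 0.900, 0.925, 0.950, 0.975,
                 1.000, 1.100, 1.200, 1.300, 1.400, 1.500, 1.600)
  k <- c(1.86e-9, 1.32e-9, 1.02e-9, 9.35e-10, 1.00e-9, 1.32e-9, 1.96e-9,
         3.60e-9, 1.09e-8, 1.39e-8, 1.64e-8, 2.23e-8, 3.35e-8, 9.15e-8,
         1.56e-7, 1.48e-7, 1.25e-7, 1.82e-7, 2.93e-7, 3.91e-7, 4.86e-7,
         1.06e-6, 2.93e-6, 3.48e-6, 2.89e-6, 1.04e-6, 9.89e-6, 1.32e-5,
         1.38e-4, 2.11e-4, 8.55e-5)
  mua_mm <- 4 * pi * k / (lambda_um * 1e-3) # lambda in mm
  data.frame(wavelength_nm = lambda_um * 1000, mua_mm = mua_mm)
}

#' Water absorption coefficient at given wavelengths
#'
#' Log-linear interpolation (linear in wavelength, linear in
#' \eqn{\log \mu_a}) of the packaged water absorption table. Queries at a
#' table knot return the knot value exactly; between knots the result lies
#' between the neighbouring knot values.
#'
#' @param wavelength_nm query wavelengths in nm; must lie within the table's
#'   coverage.
#' @param table the absorption table; defaults to [water_absorption_table()].
#' @return absorption coefficients in mm^-1.
#' @export
water_mua <- function(wavelength_nm, table = water_absorption_table()) {
  rng <- range(table$wavelength_nm)
  if (any(wavelength_nm < rng[1] - 1e-9) || any(wavelength_nm > rng[2] + 1e-9))
    top_error(sprintf("Wavelength outside water-table coverage [%g, %g] nm.",
                      rng[1], rng[2]),
              "tendonoptics_domain_error")
  exp(approx(table$wavelength_nm, log(table$mua_mm),
             xout = wavelength_nm, rule = 1)$y)
}

#' Tissue absorption model: water-scaled absorption
#'
#' Models bulk tissue absorption as the water absorption spectrum scaled by
#' the tissue water volume fraction:
#' \eqn{\mu_a(\lambda) = W_t\, \mu_{a,water}(\lambda)}. Collagen and other
#' chromophores are deliberately not modeled; over 400-1600 nm water
#' dominates the absorption of tendon.
#'
#' @param wavelength_nm wavelengths in nm.
#' @param Wt water volume fraction in \eqn{[0, 1]}.
#' @param table water absorption table, see [water_mua()].
#' @return absorption coefficients in mm^-1.
#' @export
mua_model <- function(wavelength_nm, Wt, table = water_absorption_table()) {
  if (!is.finite(Wt) || Wt < 0 || Wt > 1)
    top_error("`Wt` must lie in [0, 1].", "tendonoptics_domain_error")
  Wt * water_mua(wavelength_nm, table)
}

#' Power-law reduced scattering spectrum
#'
#' Evaluates the reduced scattering model
#' \eqn{\mu_s'(\lambda) = a\, (\lambda / 500\,\mathrm{nm})^{-b}}, where `a`
#' is the reduced scattering coefficient at the 500 nm reference wavelength
#' (mm^-1) and `b` is the dimensionless scattering power. The 500 nm
#' reference is chosen because water absorption is negligible there, so
#' integrating-sphere measurements at that wavelength are scattering
#' dominated.
#'
#' @param wavelength_nm wavelengths in nm.
#' @param a reduced scattering at 500 nm, mm^-1 (> 0).
#' @param b scattering power (dimensionless).
#' @return reduced scattering coefficients in mm^-1.
#' @examples
#' musp_model(800, a = 1.54, b = 2.10) # transverse tendon in saline
#' @export
musp_model <- function(wavelength_nm, a, b) {
  if (!is.finite(a) || a <= 0)
    top_error("`a` must be positive.", "tendonoptics_domain_error")
  a * (wavelength_nm / 500)^(-b)
}

#' Scattering coefficient and mean free path from reduced scattering
#'
#' Converts a reduced scattering coefficient and anisotropy into the
#' scattering coefficient \eqn{\mu_s = \mu_s' / (1 - g)} and the scattering
#' mean free path \eqn{mfp = 1/\mu_s}. The mean free path indicates whether
#' a thin slice is in the single-scattering regime (thickness much smaller
#' than mfp).
#'
#' @param musp reduced scattering coefficient, mm^-1 (> 0).
#' @param g anisotropy factor, \eqn{0 \le g < 1}.
#' @return a list with `mus` (mm^-1) and `mfp` (mm).
#' @examples
#' derived_scattering(19.6, 0.80) # mus = 98 mm^-1, mfp = 0.010 mm
#' @export
derived_scattering <- function(musp, g) {
  if (!all(is.finite(g)) || any(g < 0) || any(g >= 1))
    top_error("`g` must satisfy 0 <= g < 1.", "tendonoptics_domain_error")
  if (!all(is.finite(musp)) || any(musp <= 0))
    top_error("`musp` must be positive.", "tendonoptics_domain_error")
  mus <- musp / (1 - g)
  list(mus = mus, mfp = 1 / mus)
}
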