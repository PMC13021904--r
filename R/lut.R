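#' Build a Monte-Carlo reflectance/transmittance lookup table
#'
#' Simulates [run_slab()] on every cell of a `(mua, musp)` grid at fixed
#' anisotropy, thickness and refractive indices, producing the lookup table
#' used by the spectral inversion. Each cell converts the reduced scattering
#' coordinate through \eqn{\mu_s = \mu_s'/(1-g)} and runs an independent
#' stream (seed offset by the cell index), so a table is reproducible from
#' its metadata alone.
#'
#' Default grids are log-spaced and sized for 1.5 mm tendon slices; the
#' ranges can (and should) be adapted to bracket the data being inverted --
#' [invert_spectra()] does this expansion automatically when needed.
#'
#' @param g anisotropy factor used for all cells.
#' @param geom a [slab_geometry()].
#' @param mua_grid ascending absorption grid, mm^-1 (may start at 0).
#' @param musp_grid ascending positive reduced scattering grid, mm^-1.
#' @param n_photons photon packets per cell.
#' @param seed base seed; cell `(i, j)` uses `seed + (j-1)*n_mua + i - 1`.
#' @param n_tissue tissue refractive index.
#' @return an object of class `optics_lut` with `mua_grid`, `musp_grid`,
#'   matrices `Rd` and `Tt` (rows follow `mua_grid`), and `meta`.
#' @export
build_lut <- function(g, geom = slab_geometry(1.5),
                      mua_grid = c(0, 10^seq(-4, 0, length.out = 24)),
                      musp_grid = 10^seq(log10(0.01), log10(30), length.out = 25),
                      n_photons = 1e4, seed = 1, n_tissue = 1.40) {
  stopifnot(inherits(geom, "slab_geometry"))
  if (is.unsorted(mua_grid, strictly = TRUE) || any(mua_grid < 0))
    top_error("`mua_grid` must be ascending and >= 0.",
              "tendonoptics_domain_error")
  if (is.unsorted(musp_grid, strictly = TRUE) || any(musp_grid <= 0))
    top_error("`musp_grid` must be ascending and positive.",
              "tendonoptics_domain_error")
  nm <- length(mua_grid); ns <- length(musp_grid)
  Rd <- Tt <- matrix(NA_real_, nm, ns)
  for (j in seq_len(ns)) {
    for (i in seq_len(nm)) {
      props <- optical_properties(mua = mua_grid[i], musp = musp_grid[j],
                                  g = g, n = n_tissue)
      cell_seed <- seed + (j - 1) * nm + i - 1
      out <- run_slab(props, geom, n_photons = n_photons, seed = cell_seed)
      Rd[i, j] <- out$Rd
      Tt[i, j] <- out$Tt
    }
  }
  structure(
    list(mua_grid = mua_grid, musp_grid = musp_grid, Rd = Rd, Tt = Tt,
         meta = list(g = g, thickness_mm = geom$thickness,
                     n_tissue = n_tissue, n_above = geom$n_above,
                     n_below = geom$n_below, n_photons = n_photons,
                     seed = seed)),
    class = "optics_lut")
}

#' @export
print.optics_lut <- function(x, ...) {
  cat(sprintf("Rd/Tt lookup table: %d x %d cells, g = %g, thickness = %g mm, %g photons/cell\n",
              length(x$mua_grid), length(x$musp_grid), x$meta$g,
              x$meta$thickness_mm, x$meta$n_photons))
  cat(sprintf("  mua in [%g, %g] mm^-1; musp in [%g, %g] mm^-1\n",
              min(x$mua_grid), max(x$mua_grid),
              min(x$musp_grid), max(x$musp_grid)))
  invisible(x)
}

# Bilinear interpolation of both tables at (mua, musp) query points.
# clamp = TRUE projects out-of-range queries onto the grid edge (used inside
# optimization); clamp = FALSE raises a coverage error.
lut_interp <- function(lut, mua, musp, clamp = FALSE) {
  stopifnot(inherits(lut, "optics_lut"))
  out_lo <- mua < min(lut$mua_grid) | musp < min(lut$musp_grid)
  out_hi <- mua > max(lut$mua_grid) | musp > max(lut$musp_grid)
  bad <- which(out_lo | out_hi)
  if (length(bad) && !clamp)
    top_error(
      sprintf("LUT grid does not cover %d quer%s (e.g. mua = %.3g, musp = %.3g mm^-1); extend the grid.",
              length(bad), if (length(bad) == 1) "y" else "ies",
              mua[bad[1]], musp[bad[1]]),
      "tendonoptics_lut_coverage", queries = bad)
  mua <- pmin(pmax(mua, min(lut$mua_grid)), max(lut$mua_grid))
  musp <- pmin(pmax(musp, min(lut$musp_grid)), max(lut$musp_grid))

  ia <- findInterval(mua, lut$mua_grid, all.inside = TRUE)
  js <- findInterval(musp, lut$musp_grid, all.inside = TRUE)
  fa <- (mua - lut$mua_grid[ia]) /
    (lut$mua_grid[ia + 1] - lut$mua_grid[ia])
  fs <- (musp - lut$musp_grid[js]) /
    (lut$musp_grid[js + 1] - lut$musp_grid[js])
  bil <- function(M) {
    (1 - fa) * (1 - fs) * M[cbind(ia, js)] +
      fa * (1 - fs) * M[cbind(ia + 1, js)] +
      (1 - fa) * fs * M[cbind(ia, js + 1)] +
      fa * fs * M[cbind(ia + 1, js + 1)]
  }
  list(Rd = bil(lut$Rd), Tt = bil(lut$Tt))
}

#' Check the physical sanity of a lookup table
#'
#' Verifies the expected qualitative structure of a reflectance and
#' transmittance table: entries in \[0, 1\], energy bound
#' \eqn{R_d + T_t \le 1} within Monte-Carlo error, and transmittance
#' non-increasing along the absorption axis.
#'
#' @param lut an `optics_lut`.
#' @param mc_tol slack allowed on the monotonicity/energy checks to absorb
#'   Monte-Carlo noise (absolute, on fractions).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_lut <- function(lut, mc_tol = 3 / sqrt(lut$meta$n_photons)) {
  stopifnot(inherits(lut, "optics_lut"))
  if (any(lut$Rd < 0) || any(lut$Rd > 1) || any(lut$Tt < 0) || any(lut$Tt > 1))
    top_error("LUT entries outside [0, 1].", "tendonoptics_lut_invalid")
  if (any(lut$Rd + lut$Tt > 1 + mc_tol))
    top_error("LUT violates Rd + Tt <= 1 beyond Monte-Carlo error.",
              "tendonoptics_lut_invalid")
  dT <- apply(lut$Tt, 2, diff)
  if (any(dT > mc_tol))
    top_error("LUT transmittance increases along the mua axis beyond Monte-Carlo error.",
              "tendonoptics_lut_invalid")
  invisible(TRUE)
}

#' Write / read a lookup table (JSON)
#'
#' Lookup tables are serialized as a single JSON document holding both grids,
#' both tables and the full metadata (anisotropy, thickness, refractive
#' indices, photon count, seed), so any table can be regenerated or audited
#' from the file alone. [lut_to_csv()] additionally exports a long-format
#' CSV for inspection in other tools.
#'
#' @param lut an `optics_lut`.
#' @param path file path.
#' @return `write_lut()` returns `path` invisibly; `read_lut()` returns the
#'   `optics_lut`.
#' @export
write_lut <- function(lut, path) {
  stopifnot(inherits(lut, "optics_lut"))
  obj <- list(mua_grid = lut$mua_grid, musp_grid = lut$musp_grid,
              Rd = lut$Rd, Tt = lut$Tt, meta = lut$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mua_grid = as.numeric(obj$mua_grid),
                 musp_grid = as.numeric(obj$musp_grid),
                 Rd = matrix(unlist(obj$Rd), length(obj$mua_grid),
                             length(obj$musp_grid)),
                 Tt = matrix(unlist(obj$Tt), length(obj$mua_grid),
                             length(obj$musp_grid)),
                 meta = obj$meta),
            class = "optics_lut")
}

#' @rdname write_lut
#' @export
lut_to_csv <- function(lut, path) {
  stopifnot(inherits(lut, "optics_lut"))
  df <- expand.grid(mua = lut$mua_grid, musp = lut$musp_grid)
  df$Rd <- as.vector(lut$Rd)
  df$Tt <- as.vector(lut$Tt)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
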