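test_that("spectra sampled at exact LUT nodes are recovered self-consistently", {
  # construct a measurement whose (mua, musp) trajectory passes exactly
  # through table nodes, so a perfect fit with zero residual exists
  Wt0 <- 0.5; a0 <- 1.2; b0 <- 1.8
  lam <- seq(500, 1200, length.out = 15)
  mua0 <- mua_model(lam, Wt0)
  musp0 <- musp_model(lam, a0, b0)
  lut <- build_lut(g = 0.7, geom = slab_geometry(1.5),
                   mua_grid = sort(unique(c(0, mua0, max(mua0) * 2))),
                   musp_grid = sort(unique(c(musp0, min(musp0) / 2,
                                             max(musp0) * 2))),
                   n_photons = 3e3, seed = 31)
  node <- tendonoptics:::lut_interp(lut, mua0, musp0)
  meas <- spectrum_measurement(lam, node$Rd, node$Tt, thickness_mm = 1.5)
  fit <- invert_spectra(meas, lut)
  expect_lt(fit$residual, 1e-12)
  expect_equal(fit$Wt, Wt0, tolerance = 1e-3)
  expect_equal(fit$a, a0, tolerance = 1e-3)
  expect_equal(fit$b, b0, tolerance = 1e-3)
  expect_equal(fit$K, 1, tolerance = 1e-3)
})

test_that("parameters are recovered from noisy forward-simulated spectra", {
  lut <- test_lut()
  truth <- spectra_truth(Wt = 0.65, a = 1.5, b = 2.1, K_true = 1.2,
                         g = 0.70,
                         wavelength_nm = seq(450, 1250, length.out = 25),
                         n_photons = 1e4, noise_rel = 0.01)
  errs <- t(vapply(1:20, function(r) {
    meas <- gen_spectra(truth, seed = 300 + 17 * r)
    fit <- invert_spectra(meas, lut, auto_expand = FALSE)
    c(a = abs(fit$a - truth$a) / truth$a, b = abs(fit$b - truth$b))
  }, numeric(2)))
  expect_lt(max(errs[, "a"]), 0.10)
  expect_lt(max(errs[, "b"]), 0.30)
})

test_that("water content saturates at its upper bound when truth exceeds it", {
  lut <- test_lut()
  truth <- spectra_truth(Wt = 0.80, a = 1.5, b = 2.1, K_true = 1.2,
                         g = 0.70,
                         wavelength_nm = seq(450, 1250, length.out = 25),
                         n_photons = 1e4, noise_rel = 0)
  fit <- invert_spectra(gen_spectra(truth, seed = 55), lut,
                        auto_expand = FALSE)
  expect_equal(fit$Wt, 0.65, tolerance = 1e-6)
})

test_that("a common scale on the data moves only the loss factor K", {
  lut <- test_lut()
  truth <- spectra_truth(Wt = 0.65, a = 1.5, b = 2.1, K_true = 1.0,
                         g = 0.70,
                         wavelength_nm = seq(450, 1250, length.out = 20),
                         n_photons = 1e4, noise_rel = 0)
  meas <- gen_spectra(truth, seed = 8)
  fit1 <- invert_spectra(meas, lut, auto_expand = FALSE)
  cfac <- 0.8
  meas2 <- spectrum_measurement(meas$wavelength_nm, meas$Rd * cfac,
                                meas$Tt * cfac, thickness_mm = 1.5)
  fit2 <- invert_spectra(meas2, lut, auto_expand = FALSE)
  expect_equal(fit2$K, fit1$K / cfac, tolerance = 0.01)
  expect_equal(fit2$a, fit1$a, tolerance = 0.02 * fit1$a)
  expect_equal(fit2$b, fit1$b, tolerance = 0.02)
  expect_equal(fit2$Wt, fit1$Wt, tolerance = 0.02)
})

test_that("recovered scattering is insensitive to the assumed LUT anisotropy", {
  truth <- spectra_truth(Wt = 0.65, a = 1.5, b = 2.1, K_true = 1.2,
                         g = 0.70,
                         wavelength_nm = seq(450, 1250, length.out = 20),
                         n_photons = 1e4, noise_rel = 0)
  meas <- gen_spectra(truth, seed = 123)
  musp633 <- vapply(c(0.67, 0.90), function(gv) {
    lut <- build_lut(g = gv, geom = slab_geometry(1.5),
                     mua_grid = c(0, 10^seq(-5, log10(0.15), length.out = 13)),
                     musp_grid = 10^seq(log10(0.12), log10(3.5),
                                        length.out = 14),
                     n_photons = 1e4, seed = 500 + round(100 * gv))
    fit <- invert_spectra(meas, lut, auto_expand = FALSE)
    musp_model(633, fit$a, fit$b)
  }, numeric(1))
  expect_lt(abs(musp633[2] - musp633[1]) / musp633[1], 0.10)
})

test_that("inversion guards its preconditions", {
  lut <- test_lut()
  short <- spectrum_measurement(seq(500, 600, length.out = 5),
                                rep(0.2, 5), rep(0.5, 5), thickness_mm = 1.5)
  expect_error(invert_spectra(short, lut),
               class = "tendonoptics_domain_error")
  thick <- spectrum_measurement(seq(500, 1000, length.out = 12),
                                rep(0.2, 12), rep(0.5, 12), thickness_mm = 2)
  expect_error(invert_spectra(thick, lut),
               class = "tendonoptics_geometry_mismatch")
  expect_error(spectrum_measurement(c(500, 600), c(1.7, 0.2), c(0.1, 0.1),
                                    thickness_mm = 1.5),
               class = "tendonoptics_domain_error")
})
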