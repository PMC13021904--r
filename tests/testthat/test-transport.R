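test_that("HG deflection sampling matches the analytic distribution", {
  expect_equal(sample_hg_deflection(0, u = 0.75), 0.5)
  expect_equal(sample_hg_deflection(0, u = 0.5), 0.0)
  expect_equal(sample_hg_deflection(0, u = c(0, 0.25)), c(-1, -0.5))
  expect_error(sample_hg_deflection(1, u = 0.5),
               class = "tendonoptics_domain_error")

  draws <- sample_hg_deflection(0.9, n = 1e5, seed = 4)
  expect_true(all(draws >= -1 & draws <= 1))
  expect_equal(mean(draws), 0.90, tolerance = 0.01 / 0.9)

  # Kolmogorov-Smirnov against the closed-form CDF of cos(theta)
  for (g in c(0.3, 0.75)) {
    d <- sample_hg_deflection(g, n = 1e5, seed = 9)
    ks <- suppressWarnings(ks.test(d, function(x) hg_cdf(x, g)))
    expect_gt(ks$p.value, 1e-3)
  }
})

test_that("scattering-free slab reduces to Beer-Lambert", {
  p <- optical_properties(mua = 0.1, mus = 0, g = 0, n = 1.0)
  out <- run_slab(p, slab_geometry(1.5), n_photons = 1e6, seed = 7)
  expect_equal(out$Tt, exp(-0.15), tolerance = 0.005)
  expect_equal(out$Rd, 0)
  expect_equal(out$Rd + out$Tt + out$A, 1, tolerance = 1e-12)
})

test_that("energy is conserved and seeds are reproducible", {
  p <- optical_properties(mua = 0.05, mus = 3, g = 0.8, n = 1.0)
  g <- slab_geometry(1.5)
  out <- run_slab(p, g, n_photons = 1e5, seed = 3)
  expect_lt(abs(1 - (out$Rd + out$Tt + out$A)), 1e-3)

  # no absorption: everything leaves the slab
  p0 <- optical_properties(mua = 0, mus = 5, g = 0.8, n = 1.0)
  out0 <- run_slab(p0, g, n_photons = 2e5, seed = 3)
  expect_equal(out0$Rd + out0$Tt, 1, tolerance = 3 / sqrt(2e5))
  expect_equal(out0$A, 0)

  # bit-identical tallies for identical (seed, n, props)
  expect_identical(run_slab(p, g, n_photons = 2e4, seed = 99),
                   run_slab(p, g, n_photons = 2e4, seed = 99))
  expect_false(identical(run_slab(p, g, n_photons = 2e4, seed = 99),
                         run_slab(p, g, n_photons = 2e4, seed = 100)))
})

test_that("slab engine reproduces the classic albedo-0.9 finite-slab benchmark", {
  # matched boundaries, albedo 0.9, g = 0.75, optical thickness 2:
  # tabulated radiative-transfer values Rd = 0.09739, Tt = 0.66096
  p <- optical_properties(mua = 1, mus = 9, g = 0.75, n = 1.0)
  out <- run_slab(p, slab_geometry(0.2), n_photons = 5e5, seed = 11)
  se <- sqrt(0.0974 * (1 - 0.0974) / 5e5)
  expect_lt(abs(out$Rd - 0.09739), 3 * se)
  expect_lt(abs(out$Tt - 0.66096), 3 * sqrt(0.661 * 0.339 / 5e5))
})

test_that("weighted engine agrees with an independent analog MC", {
  # diffusive regime, matched boundaries, isotropic scattering
  mua <- 0.01; mus <- 10; d <- 1.5
  oracle <- brute_slab(mua, mus, g = 0, d = d, n = 4000, seed = 21)
  p <- optical_properties(mua = mua, mus = mus, g = 0, n = 1.0)
  out <- run_slab(p, slab_geometry(d), n_photons = 2e5, seed = 22)
  expect_lt(abs(out$Rd - oracle$Rd), 2 * oracle$se_Rd + 0.002)
  expect_lt(abs(out$Tt - oracle$Tt), 2 * oracle$se_Tt + 0.002)
})

test_that("slab results are insensitive to g at fixed reduced scattering", {
  g <- slab_geometry(1.5)
  a <- run_slab(optical_properties(mua = 0.001, musp = 1, g = 0.7, n = 1.4),
                g, n_photons = 2e5, seed = 21)
  b <- run_slab(optical_properties(mua = 0.001, musp = 1, g = 0.9, n = 1.4),
                g, n_photons = 2e5, seed = 22)
  expect_lt(abs(b$Rd - a$Rd) / a$Rd, 0.05)
  expect_lt(abs(b$Tt - a$Tt) / a$Tt, 0.05)
})

test_that("volume engine matches the slab engine and conserves weight", {
  # wide, thin volume with matched faces behaves like a slab
  geom <- volume_geometry(dims = c(30, 30, 1.5), voxel = 0.5,
                          beam_diameter = 0.2, boundary = "matched")
  p <- optical_properties(mua = 1, mus = 9, g = 0.75, n = 1.0)
  m <- score_fluence(p, geom, n_photons = 1e5, seed = 5)
  ref <- run_slab(p, slab_geometry(1.5), n_photons = 2e5, seed = 6)
  expect_equal(m$escaped$zlo, ref$Rd, tolerance = 0.02)
  expect_equal(m$escaped$zhi, ref$Tt, tolerance = 0.2)
  # weight ledger: delivered = absorbed + escaped (roulette tolerance)
  total <- m$absorbed + sum(unlist(m$escaped)) + m$Rsp
  expect_lt(abs(1 - total), 1e-3)
  expect_true(all(m$phi >= 0))
  expect_gte(m$transmitted_fraction, 0)
  expect_lte(m$transmitted_fraction, 1)
})

test_that("absorbing-only volume reproduces the Beer-Lambert fluence decay", {
  p <- optical_properties(mua = 0.1, mus = 0, g = 0, n = 1.0)
  geom <- volume_geometry(dims = c(10, 10, 50), voxel = 0.5,
                          boundary = "matched")
  m <- score_fluence(p, geom, n_photons = 1e5, seed = 3,
                     profile_radius = 0.6, mueff_window = c(2, 48))
  expect_equal(m$mueff, 0.1, tolerance = 0.02)
  expect_lt(abs(1 - (m$absorbed + sum(unlist(m$escaped)))), 1e-3)
})

test_that("invalid transport inputs raise domain errors", {
  expect_error(optical_properties(mua = -1, mus = 1, g = 0),
               class = "tendonoptics_domain_error")
  expect_error(optical_properties(mua = 0.1, mus = 1, g = 1.2),
               class = "tendonoptics_domain_error")
  expect_error(slab_geometry(-1), class = "tendonoptics_domain_error")
  expect_error(run_slab(optical_properties(0.1, 1, 0.5),
                        slab_geometry(1.5), n_photons = 10),
               class = "tendonoptics_domain_error")
  expect_error(volume_geometry(dims = c(10, 10, 10.3), voxel = 0.5),
               class = "tendonoptics_domain_error")
  # derived reduced scattering is consistent on construction
  p <- optical_properties(mua = 0, musp = 2, g = 0.6)
  expect_equal(p$mus * (1 - p$g), p$musp)
})
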