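test_that("hg_phase matches closed forms and rejects invalid g", {
  expect_equal(hg_phase(0.7, 0), 1 / (4 * pi))
  expect_equal(hg_phase(c(0, 1, 2), 0), rep(1 / (4 * pi), 3))
  # forward peak for g = 0.5: (1 + g) / ((1 - g)^2 * 4 pi)
  expect_equal(hg_phase(0, 0.5), 6 / (4 * pi), tolerance = 1e-12)
  expect_error(hg_phase(0, 1), class = "tendonoptics_domain_error")
  expect_error(hg_phase(0, -1.2), class = "tendonoptics_domain_error")
})

test_that("hg_phase integrates to one over the sphere for random g", {
  set.seed(11)
  gs <- runif(200, -0.99, 0.99)
  for (g in gs) {
    v <- integrate(function(th) hg_phase(th, g) * 2 * pi * sin(th),
                   0, pi, rel.tol = 1e-10)$value
    expect_lt(abs(v - 1), 1e-6)
  }
})

test_that("double_hg_model applies the Lambertian cosine factor", {
  f <- double_hg_fit(K1 = 1, g1 = 0, K2 = 0, g2 = 0)
  expect_equal(double_hg_model(0, f), 1 / (4 * pi))
  expect_equal(double_hg_model(pi / 2, f), 0, tolerance = 1e-15)
  f2 <- double_hg_fit(K1 = 2, g1 = 0, K2 = 0, g2 = 0.5)
  expect_equal(double_hg_model(pi / 3, f2), 0.5 * 2 / (4 * pi),
               tolerance = 1e-12)
  # any parameter set vanishes at 90 degrees
  f3 <- double_hg_fit(K1 = 1.3, g1 = 0.9, K2 = 0.4, g2 = 0.3)
  expect_equal(double_hg_model(pi / 2, f3), 0, tolerance = 1e-15)
})

test_that("effective anisotropy of a single HG lobe equals its g parameter", {
  for (g in c(-0.9, 0, 0.5, 0.6, 0.9, 0.99)) {
    f <- effective_anisotropy(double_hg_fit(1, g, 0, 0))
    expect_lt(abs(f$g1_eff - g), 1e-4)
    expect_lt(abs(f$g_eff - g), 1e-4)
  }
})

test_that("mixture g_eff is the K-weighted mean of the lobe anisotropies", {
  f <- effective_anisotropy(double_hg_fit(1, 0.9, 1, 0.5))
  expect_equal(f$g_eff, 0.7, tolerance = 1e-4)
  # two identical lobes collapse to g regardless of the K split
  f2 <- effective_anisotropy(double_hg_fit(0.3, 0.8, 2.7, 0.8))
  expect_equal(f2$g_eff, 0.8, tolerance = 1e-4)
  set.seed(42)
  for (i in 1:20) {
    K <- runif(2, 0.1, 5)
    g <- runif(2, 0, 0.99)
    f <- effective_anisotropy(double_hg_fit(K[1], g[1], K[2], g[2]))
    expect_lt(abs(f$g_eff - sum(K * g) / sum(K)), 1e-4)
    expect_gte(f$g_eff, min(f$g1_eff, f$g2_eff) - 1e-9)
    expect_lte(f$g_eff, max(f$g1_eff, f$g2_eff) + 1e-9)
  }
})

test_that("noiseless two-lobe scans are recovered to high accuracy", {
  truth <- goniometer_truth(K1 = 1.0, g1 = 0.94, K2 = 0.5, g2 = 0.65,
                            noise_rel = 0, floor_frac = 0)
  fit <- fit_double_hg(gen_goniometer_scan(truth, seed = 1))
  expect_lt(abs(fit$K1 - 1.0), 1e-3)
  expect_lt(abs(fit$g1 - 0.94), 1e-3)
  expect_lt(abs(fit$K2 - 0.5), 1e-3)
  expect_lt(abs(fit$g2 - 0.65), 1e-3)
  expect_gte(fit$g1, fit$g2)

  # fit consistency: objective at the optimum <= objective at the truth
  scan <- gen_goniometer_scan(truth, seed = 1)
  fold <- tendonoptics:::fold_scan(scan$theta_deg, scan$intensity)
  th <- fold$theta_deg * pi / 180
  w <- 2 * pi * abs(sin(th)) * mean(diff(fold$theta_deg)) * pi / 180
  obj <- function(f) sum((w * double_hg_model(th, f) - w * fold$intensity)^2)
  expect_lte(obj(fit), obj(double_hg_fit(1.0, 0.94, 0.5, 0.65)) + 1e-10)
})

test_that("single-lobe scans recover a negligible second lobe", {
  truth <- goniometer_truth(K1 = 1, g1 = 0.9, K2 = 0, g2 = 0.3,
                            noise_rel = 0, floor_frac = 0)
  fit <- fit_double_hg(gen_goniometer_scan(truth, seed = 2))
  expect_equal(fit$g1, 0.9, tolerance = 2e-3)
  total <- fit$K1 + fit$K2
  # either K2 vanished or both lobes merged at g = 0.9
  expect_true(fit$K2 < 1e-6 * fit$K1 || abs(fit$g2 - 0.9) < 2e-3)
  expect_equal(total, 1, tolerance = 2e-3)
})

test_that("g_eff is robust to 2 percent multiplicative noise", {
  truth <- goniometer_truth(K1 = 1.0, g1 = 0.90, K2 = 0.55, g2 = 0.45,
                            noise_rel = 0.02, floor_frac = 0)
  g_true <- effective_anisotropy(
    double_hg_fit(truth$K1, truth$g1, truth$K2, truth$g2))$g_eff
  devs <- vapply(1:50, function(s) {
    fit <- fit_double_hg(gen_goniometer_scan(truth, seed = 1000 + s))
    abs(fit$g_eff - g_true)
  }, numeric(1))
  expect_lt(max(devs), 0.02)
})

test_that("degenerate scans are rejected with classed errors", {
  th <- seq(-50, 50, by = 1)
  expect_error(fit_double_hg(angular_scan(th, rep(0, length(th)))),
               class = "tendonoptics_degenerate_scan")
  # stray-light floor only: constant intensity carries no angular information
  truth <- goniometer_truth(K1 = 0, g1 = 0.9, K2 = 0, g2 = 0.3,
                            noise_rel = 0.02, floor_frac = 0.01)
  expect_error(fit_double_hg(gen_goniometer_scan(truth, seed = 3)),
               class = "tendonoptics_degenerate_scan")
  # too few angles
  expect_error(
    fit_double_hg(angular_scan(seq(-10, 10, 1), abs(seq(-10, 10, 1)) + 1)),
    class = "tendonoptics_domain_error")
})

test_that("angular scans validate, sort and clip their inputs", {
  expect_warning(s <- angular_scan(c(2, 1, 3), c(5, 6, 7)),
                 "not sorted")
  expect_equal(s$theta_deg, c(1, 2, 3))
  expect_equal(s$intensity, c(6, 5, 7))
  expect_warning(s2 <- angular_scan(1:3, c(-1, 2, 3)), "clipped")
  expect_equal(s2$intensity, c(0, 2, 3))
  expect_error(angular_scan(c(-100, 0, 50), c(1, 1, 1)),
               class = "tendonoptics_domain_error")
  avg <- average_scans(list(angular_scan(1:41, rep(2, 41)),
                            angular_scan(1:41, rep(4, 41))))
  expect_equal(avg$intensity, rep(3, 41))
  expect_error(average_scans(list(angular_scan(1:41, rep(2, 41)),
                                  angular_scan(2:42, rep(2, 41)))),
               class = "tendonoptics_domain_error")
})
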