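test_that("generators are deterministic and leave the global RNG alone", {
  truth <- goniometer_truth()
  s1 <- gen_goniometer_scan(truth, seed = 5)
  s2 <- gen_goniometer_scan(truth, seed = 5)
  expect_identical(s1, s2)
  s3 <- gen_goniometer_scan(truth, seed = 6)
  expect_false(identical(s1$intensity, s3$intensity))

  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_goniometer_scan(truth, seed = 5))
  expect_identical(runif(1), before)

  tr <- spectra_truth(wavelength_nm = seq(500, 900, length.out = 10),
                      n_photons = 2e3)
  expect_identical(gen_spectra(tr, seed = 2), gen_spectra(tr, seed = 2))
})

test_that("noiseless scans equal the model and noise has the nominal size", {
  truth <- goniometer_truth(K1 = 1, g1 = 0.9, K2 = 0.4, g2 = 0.5,
                            noise_rel = 0, floor_frac = 0)
  scan <- gen_goniometer_scan(truth, seed = 1)
  model <- double_hg_model(abs(truth$theta_deg) * pi / 180,
                           double_hg_fit(1, 0.9, 0.4, 0.5))
  expect_equal(scan$intensity, model)

  # empirical relative sd within 20 percent of nominal over ~1e3 angles
  big <- goniometer_truth(K1 = 1, g1 = 0.9, K2 = 0.4, g2 = 0.5,
                          noise_rel = 0.02, floor_frac = 0,
                          theta_deg = seq(-50, 50, length.out = 1001))
  scan2 <- gen_goniometer_scan(big, seed = 7)
  model2 <- double_hg_model(abs(big$theta_deg) * pi / 180,
                            double_hg_fit(1, 0.9, 0.4, 0.5))
  rel <- scan2$intensity / model2 - 1
  expect_lt(abs(sd(rel) - 0.02) / 0.02, 0.20)
})

test_that("generate-then-fit round trip recovers g_eff at 2 percent noise", {
  truth <- goniometer_truth(K1 = 1.0, g1 = 0.94, K2 = 0.5, g2 = 0.65,
                            noise_rel = 0.02, floor_frac = 0)
  g_true <- effective_anisotropy(double_hg_fit(1.0, 0.94, 0.5, 0.65))$g_eff
  fit <- fit_double_hg(gen_goniometer_scan(truth, seed = 1))
  expect_lt(abs(fit$g_eff - g_true), 0.02)
})

test_that("lossless spectra conserve energy and K_true sets observed losses", {
  # negligible-absorption band, matched K_true = 1: Rd + Tt ~ 1 - specular
  tr <- spectra_truth(Wt = 0, a = 1.5, b = 2.1, K_true = 1, g = 0.7,
                      wavelength_nm = seq(480, 660, length.out = 10),
                      n_photons = 2e4, noise_rel = 0)
  m <- gen_spectra(tr, seed = 3)
  rsp <- ((1.4 - 1) / (1.4 + 1))^2
  expect_equal(m$Rd + m$Tt, rep(1 - rsp, 10), tolerance = 0.02)

  # a realistic loss factor shrinks the observed sum near 500 nm to ~0.8
  tr2 <- spectra_truth(Wt = 0.65, a = 1.54, b = 2.10, K_true = 1.22,
                       g = 0.70, wavelength_nm = seq(480, 660, length.out = 10),
                       n_photons = 2e4, noise_rel = 0)
  m2 <- gen_spectra(tr2, seed = 4)
  expect_equal(m2$Rd[2] + m2$Tt[2], 0.82, tolerance = 0.05)
})

test_that("fixture suite is reproducible and its manifest honours invariants", {
  dir1 <- file.path(tempdir(), "fix1")
  dir2 <- file.path(tempdir(), "fix2")
  unlink(c(dir1, dir2), recursive = TRUE)
  man1 <- gen_fixture_suite(dir1, seed = 3)
  man2 <- gen_fixture_suite(dir2, seed = 3)
  files <- sort(list.files(dir1))
  expect_identical(files, sort(list.files(dir2)))
  expect_gt(length(files), 4)
  for (f in files)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # manifest truths parse and satisfy type invariants
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                             simplifyVector = TRUE)
  for (nm in names(man$files)) {
    tr <- man$files[[nm]]$truth
    if (man$files[[nm]]$type == "spectrum") {
      expect_true(tr$Wt >= 0 && tr$Wt <= 1)
      expect_gt(tr$a, 0)
      expect_gt(tr$K_true, 0)
    } else {
      expect_gte(tr$K1, 0)
      expect_true(abs(tr$g1) < 1 && abs(tr$g2) < 1)
    }
  }
  # files round-trip through the readers
  scan <- read_angular_csv(file.path(dir1, grep("^scan", files, value = TRUE)[1]))
  expect_s3_class(scan, "angular_scan")
  spec <- read_spectra_csv(file.path(dir1, grep("^spectra", files, value = TRUE)[1]))
  expect_s3_class(spec, "spectrum_measurement")
})
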