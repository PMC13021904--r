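# Independent oracles used to cross-check the compiled transport engine.
# Deliberately naive implementations with different algorithms: analog
# (unweighted) photons, rejection sampling of the phase function, and
# direction rotation via an explicit orthonormal basis.

# Analytic CDF of cos(theta) under the HG phase function.
hg_cdf <- function(ct, g) {
  if (abs(g) < 1e-12) return((ct + 1) / 2)
  (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * ct) - 1 / (1 + g))
}

# Brute-force analog Monte Carlo for a matched-boundary slab. Returns
# counts-based (Rd, Tt, A) estimates and their binomial standard errors.
brute_slab <- function(mua, mus, g, d, n = 5000, seed = 1) {
  set.seed(seed)
  mut <- mua + mus
  albedo <- mus / mut
  hg_pdf <- function(ct) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * ct)^1.5
  M <- max(hg_pdf(1), hg_pdf(-1)) * 1.05
  sample_ct <- function() {
    repeat {
      ct <- runif(1, -1, 1)
      if (runif(1) * M < hg_pdf(ct)) return(ct)
    }
  }
  refl <- trans <- 0
  for (i in seq_len(n)) {
    z <- 0; u <- c(0, 0, 1)
    repeat {
      s <- -log(runif(1)) / mut
      z2 <- z + s * u[3]
      if (z2 < 0) { refl <- refl + 1; break }
      if (z2 > d) { trans <- trans + 1; break }
      z <- z2
      if (runif(1) > albedo) break # absorbed (analog termination)
      ct <- if (abs(g) < 1e-12) runif(1, -1, 1) else sample_ct()
      st <- sqrt(1 - ct^2)
      phi <- runif(1, 0, 2 * pi)
      a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * u) * u
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      u <- ct * u + st * (cos(phi) * e1 + sin(phi) * e2)
      u <- u / sqrt(sum(u^2))
    }
  }
  list(Rd = refl / n, Tt = trans / n,
       se_Rd = sqrt(refl) / n, se_Tt = sqrt(trans) / n, n = n)
}

# Shared small lookup table for inversion tests (built once per test run).
# Grid brackets the transverse-saline-like truths used in the tests.
test_lut <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_lut(
        g = 0.70, geom = slab_geometry(1.5),
        mua_grid = c(0, 10^seq(-5, log10(0.15), length.out = 17)),
        musp_grid = 10^seq(log10(0.12), log10(3.5), length.out = 18),
        n_photons = 1e4, seed = 77)
    cache
  }
})
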