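# tendonoptics

Orientation-resolved tissue optics of tendon: an R package for quantifying
how strongly aligned fibrous tissue scatters light along versus across its
fiber axis, and what that means for delivering therapeutic light
(photobiomodulation) through it.

It is written for researchers working with two standard bench
measurements — goniometer angular scattering scans of thin tissue slices,
and integrating-sphere diffuse reflectance ($R_d$) / total transmittance
($T_t$) spectra of millimeter slabs — who want wavelength-resolved optical
coefficients and light-transport predictions out the other end.

## What it computes

**Effective anisotropy from angular scans.** Measured intensity profiles
$I_{meas}(\theta)$ over $\pm 50^\circ$ are fitted with a two-lobe
Henyey–Greenstein model with a Lambertian escape factor,

$$p_{fit}(\theta) = \cos\theta \left(K_1\, p_{HG}(\theta, g_1) + K_2\,
p_{HG}(\theta, g_2)\right),$$

by weighted least squares (azimuthal weight $2\pi|\sin\theta|\Delta\theta$).
The effective anisotropy $g_{eff}$ is the mean scattering cosine of the
fitted distribution with the cosine factor removed.

**Monte-Carlo photon transport.** A compiled weighted-packet engine
(MCML-style rules: exponential steps, per-interaction absorption, HG
deflection, Fresnel boundaries, Russian roulette) provides slab
reflectance/transmittance tallies, $(\mu_a, \mu_s') \to (R_d, T_t)$ lookup
tables, and voxelized fluence maps with a track-length estimator.

**Spectral inversion.** $R_d/T_t$ spectra (400–1600 nm) are inverted by
bounded least squares against the lookup tables for water content $W_t$
(absorption model $\mu_a = W_t\,\mu_{a,water}(\lambda)$, Hale–Querry water
table), power-law reduced scattering
$\mu_s'(\lambda) = a\,(\lambda/500\,\mathrm{nm})^{-b}$, and a loss factor
$K$ that rescales the measured spectra for sphere port losses. Derived
quantities follow $\mu_s = \mu_s'/(1-g)$ and $mfp = 1/\mu_s$.

**Transmission scenarios.** Fiber-delivered light through a
13.8 × 13.8 × 50 mm tissue volume, with on-axis depth profiles, fitted
effective attenuation $\mu_{eff}$, transmitted fractions, and an
orientation comparison (along- versus across-fiber delivery).

A synthetic-data module generates instrument-realistic scans and spectra
from known ground truth, so the whole pipeline is testable without any
measured data.

## Worked example

Fit a goniometer scan drawn from a known two-lobe truth (2% multiplicative
noise) and recover its effective anisotropy:

```r
library(tendonoptics)

truth <- goniometer_truth(K1 = 1.0, g1 = 0.90, K2 = 0.55, g2 = 0.45,
                          noise_rel = 0.02, floor_frac = 0)
scan <- gen_goniometer_scan(truth, seed = 1)
fit_double_hg(scan)
#> Two-lobe Henyey-Greenstein fit
#>   narrow lobe: K1 = 1.007, g1 = 0.8999
#>   broad lobe : K2 = 0.5529, g2 = 0.4426
#>   effective anisotropy: g1_eff = 0.900, g2_eff = 0.443, g_eff = 0.738
#>   residual: 5.656e-06
```

The narrow lobe ($g_1 \approx 0.90$) is the forward peak from the large
aligned structures, the broad lobe ($g_2 \approx 0.44$) the wide-angle
scatter from smaller ones; $g_{eff} = 0.738$ (truth: 0.740) is their
power-weighted mean cosine and is the anisotropy a transport simulation of
this sample should use.

Invert forward-simulated sphere spectra for the scattering power law
(truth: $W_t = 0.65$, $a = 1.54$ mm⁻¹, $b = 2.10$, $K = 1.22$):

```r
lut <- build_lut(g = 0.70, geom = slab_geometry(1.5),
                 mua_grid = c(0, 10^seq(-5, log10(0.15), length.out = 15)),
                 musp_grid = 10^seq(log10(0.13), log10(3.4), length.out = 16),
                 n_photons = 1e4, seed = 42)
meas <- gen_spectra(spectra_truth(Wt = 0.65, a = 1.54, b = 2.10,
                                  K_true = 1.22, g = 0.70), seed = 7)
invert_spectra(meas, lut)
#> Scattering model fit (water-scaled mua, power-law musp)
#>   Wt = 0.650, a = 1.491 mm^-1, b = 2.060, K = 1.218
#>   residual = 0.002413 over 25 wavelengths (LUT g = 0.7)
```

`a` is the reduced scattering at 500 nm (here recovered within 3%), `b`
the scattering power, and `K` the loss rescaling of the measured spectra.
The fitted power law then gives $\mu_s'$ at any wavelength, e.g.
`musp_model(800, 1.54, 2.10)` → 0.57 mm⁻¹ for light along the fibers in
saline, and `derived_scattering(19.6, 0.80)` → $\mu_s = 98$ mm⁻¹,
$mfp = 0.010$ mm for the across-fiber case at 633 nm.

A thin command-line interface wraps the same functions
(`inst/cli/tendonoptics`): `synth`, `fit-phase`, `build-lut`, `invert`,
`simulate-transmission`, `report`.

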