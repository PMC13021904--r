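#' Henyey-Greenstein phase function
#'
#' Evaluates the normalized Henyey-Greenstein (HG) phase function
#' \deqn{p_{HG}(\theta) = \frac{1}{4\pi}\,
#'   \frac{1 - g^2}{(1 + g^2 - 2 g \cos\theta)^{3/2}}}
#' in units of inverse steradians. Some printed versions of the formula drop
#' the square on \eqn{g} in the denominator; only the form above integrates
#' to one over the sphere (\eqn{\int p_{HG}\, 2\pi \sin\theta\, d\theta = 1}),
#' which is the normalization assumed everywhere in this package, so the
#' standard form is used.
#'
#' @param theta polar scattering angle(s) in radians, in \eqn{[0, \pi]}.
#' @param g anisotropy parameter, strictly inside (-1, 1).
#' @return phase-function density per steradian, same length as `theta`.
#' @examples
#' hg_phase(0, 0)          # isotropic: 1 / (4 pi)
#' hg_phase(0, 0.5)        # forward peak: 6 / (4 pi)
#' @export
hg_phase <- function(theta, g) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || abs(g) >= 1)
    top_error("`g` must be a single value strictly inside (-1, 1).",
              "tendonoptics_domain_error")
  (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos(theta))^1.5)
}

#' Two-lobe Henyey-Greenstein fit parameters
#'
#' Container for the parameters of the two-lobe HG model used to describe
#' goniometer scans of fibrous tissue: a narrow on-axis lobe
#' \eqn{p_1 = K_1 p_{HG}(\theta, g_1)} and a broad lobe
#' \eqn{p_2 = K_2 p_{HG}(\theta, g_2)}. `K1` and `K2` are scale factors in
#' arbitrary units times steradian that map the unit-normalized phase
#' functions onto detector counts. Effective anisotropies (the mean cosine of
#' each lobe and of their sum) are filled in by [effective_anisotropy()].
#'
#' @param K1,K2 lobe scale factors, \eqn{\ge 0} (a.u. sr).
#' @param g1,g2 lobe anisotropy parameters in (-1, 1).
#' @param residual value of the least-squares objective, if known.
#' @return an object of class `double_hg_fit`.
#' @export
double_hg_fit <- function(K1, g1, K2, g2, residual = NA_real_) {
  for (K in c(K1, K2))
    if (!is.finite(K) || K < 0)
      top_error("Scale factors K1, K2 must be finite and >= 0.",
                "tendonoptics_domain_error")
  for (g in c(g1, g2))
    if (!is.finite(g) || abs(g) >= 1)
      top_error("Anisotropy parameters g1, g2 must lie strictly in (-1, 1).",
                "tendonoptics_domain_error")
  structure(
    list(K1 = K1, g1 = g1, K2 = K2, g2 = g2,
         g1_eff = NA_real_, g2_eff = NA_real_, g_eff = NA_real_,
         residual = residual),
    class = "double_hg_fit")
}

#' @export
print.double_hg_fit <- function(x, ...) {
  cat("Two-lobe Henyey-Greenstein fit\n")
  cat(sprintf("  narrow lobe: K1 = %.4g, g1 = %.4f\n", x$K1, x$g1))
  cat(sprintf("  broad lobe : K2 = %.4g, g2 = %.4f\n", x$K2, x$g2))
  if (is.finite(x$g_eff))
    cat(sprintf("  effective anisotropy: g1_eff = %.3f, g2_eff = %.3f, g_eff = %.3f\n",
                x$g1_eff, x$g2_eff, x$g_eff))
  if (is.finite(x$residual))
    cat(sprintf("  residual: %.4g\n", x$residual))
  invisible(x)
}

#' Two-lobe HG model with Lambertian escape factor
#'
#' Evaluates the model fitted to goniometer data,
#' \eqn{p_{fit}(\theta) = \cos\theta\,(K_1 p_{HG}(\theta, g_1) +
#' K_2 p_{HG}(\theta, g_2))}. The cosine factor accounts for the Lambertian
#' pattern of flux escaping a flat sample surface; it makes the model vanish
#' at \eqn{\theta = \pi/2}.
#'
#' @param theta polar angle(s) in radians.
#' @param fit a [double_hg_fit()] object.
#' @return model intensities (arbitrary units), same length as `theta`.
#' @export
double_hg_model <- function(theta, fit) {
  stopifnot(inherits(fit, "double_hg_fit"))
  cos(theta) * (fit$K1 * hg_phase(theta, fit$g1) +
                fit$K2 * hg_phase(theta, fit$g2))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Adaptive Gauss-Kronrod quadrature over [0, pi]. A fixed uniform angular
# grid cannot resolve the forward lobe once g approaches 1 (its width scales
# like 1 - g), so full-range phase-function integrals use stats::integrate.
angular_integral <- function(f, rel.tol = 1e-10) {
  tryCatch(
    integrate(f, 0, pi, rel.tol = rel.tol, abs.tol = 1e-13,
              subdivisions = 1000L)$value,
    error = function(e) # peaked integrands can trip the roundoff detector
      integrate(f, 0, pi, rel.tol = 1e-8, subdivisions = 1000L)$value)
}

#' Effective anisotropy of a fitted angular distribution
#'
#' Computes the mean scattering cosine
#' \deqn{g_{eff} = \frac{\int_0^\pi \cos\theta\, p(\theta)\, 2\pi \sin\theta\,
#'  d\theta}{\int_0^\pi p(\theta)\, 2\pi \sin\theta\, d\theta}}
#' for each lobe separately (`g1_eff`, `g2_eff`) and for the two-lobe sum
#' (`g_eff`). The single-scattering phase function is recovered from the
#' fitted model by removing the Lambertian factor; because
#' \eqn{p_{fit} = \cos\theta (p_1 + p_2)}, the division by \eqn{|\cos\theta|}
#' is performed analytically as \eqn{p = p_1 + p_2}, which removes the
#' singularity at \eqn{\theta = \pi/2}.
#'
#' For a single HG lobe the mean cosine equals its `g` parameter, and for a
#' mixture of unit-normalized lobes it is the K-weighted mean
#' \eqn{(K_1 g_1 + K_2 g_2)/(K_1 + K_2)}; both identities are useful checks
#' on the quadrature.
#'
#' The integrals are evaluated with adaptive quadrature: the forward lobe
#' narrows like \eqn{1 - g} as \eqn{g \to 1}, which a fixed uniform angle
#' grid cannot resolve to the accuracy these identities are tested at.
#'
#' @param fit a [double_hg_fit()] object.
#' @return the input `fit` with `g1_eff`, `g2_eff` and `g_eff` filled in.
#' @export
effective_anisotropy <- function(fit) {
  stopifnot(inherits(fit, "double_hg_fit"))
  mean_cos <- function(p) {
    num <- angular_integral(function(th) cos(th) * p(th) * 2 * pi * sin(th))
    den <- angular_integral(function(th) p(th) * 2 * pi * sin(th))
    num / den
  }
  fit$g1_eff <- mean_cos(function(th) hg_phase(th, fit$g1))
  fit$g2_eff <- mean_cos(function(th) hg_phase(th, fit$g2))
  fit$g_eff <- if (fit$K1 + fit$K2 > 0)
    mean_cos(function(th) fit$K1 * hg_phase(th, fit$g1) +
               fit$K2 * hg_phase(th, fit$g2))
  else NA_real_
  fit
}

# Fold a signed-angle scan onto [0, max] by averaging symmetric pairs.
# Left/right asymmetry (stray light, detector floor) is reported via the
# returned `asymmetry` attribute.
fold_scan <- function(theta_deg, intensity) {
  key <- round(abs(theta_deg), 6)
  folded <- tapply(intensity, key, mean)
  th <- as.numeric(names(folded))
  o <- order(th)
  pos <- theta_deg > 0
  neg <- theta_deg < 0
  asym <- if (any(pos) && any(neg))
    mean(intensity[pos]) - mean(intensity[neg]) else 0
  list(theta_deg = th[o], intensity = as.numeric(folded)[o], asymmetry = asym)
}

#' Fit a two-lobe Henyey-Greenstein model to a goniometer scan
#'
#' Least-squares fit of [double_hg_model()] to a measured angular intensity
#' profile. Model and data are compared after azimuthal weighting under the
#' assumption of rotational symmetry: the residual at each angle is
#' \eqn{w(\theta)\,(p_{fit}(\theta) - I_{meas}(\theta))} with weight
#' \eqn{w(\theta) = 2\pi |\sin\theta| \Delta\theta}, so the fit matches the
#' azimuthally integrated scattered power. Signed angles are folded onto
#' \eqn{[0, \theta_{max}]} by averaging symmetric pairs before fitting; the
#' exact on-axis point carries zero weight (\eqn{\sin 0 = 0}), which also
#' protects the fit against pinhole artifacts near \eqn{\theta \approx 0}.
#'
#' The objective has symmetric local minima under lobe exchange, so a
#' bounded multi-start strategy is used: Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}) from 8 starting points on a coarse
#' \eqn{(g_1, g_2)} lattice with bounds \eqn{g \in [0, 0.9999]},
#' \eqn{K \ge 0}; ties are broken by lowest residual, then by larger
#' \eqn{g_1}. Lobes are returned ordered so that \eqn{g_1 \ge g_2}.
#'
#' @param scan an [angular_scan()] object (or anything coercible via
#'   `angular_scan()`), covering at least 40 distinct angles on both sides
#'   of zero.
#' @return a [double_hg_fit()] with effective anisotropies and the residual
#'   (sum of squared weighted residuals) populated.
#' @export
fit_double_hg <- function(scan) {
  scan <- as_angular_scan(scan)
  th_deg <- scan$theta_deg
  I <- scan$intensity

  if (length(unique(th_deg)) < 40 || !(any(th_deg > 0) && any(th_deg < 0)))
    top_error("Scan must cover at least 40 distinct angles spanning both signs of theta.",
              "tendonoptics_domain_error")
  if (all(I == 0))
    top_error("All intensities are zero: degenerate scan.",
              "tendonoptics_degenerate_scan")

  f <- fold_scan(th_deg, I)
  if (sd(f$intensity) / max(mean(f$intensity), .Machine$double.eps) < 1e-3)
    top_error("Scan has no angular structure (constant intensity): degenerate scan.",
              "tendonoptics_degenerate_scan")

  th <- f$theta_deg * pi / 180
  dth <- mean(diff(f$theta_deg)) * pi / 180
  w <- 2 * pi * abs(sin(th)) * dth
  y <- w * f$intensity

  model_w <- function(par) {
    # par = (K1, g1, K2, g2)
    w * cos(th) * (par[1] * hg_phase(th, min(par[2], 0.9999)) +
                   par[3] * hg_phase(th, min(par[4], 0.9999)))
  }
  resid_fn <- function(par) model_w(par) - y

  # linear least squares for (K1, K2) at fixed (g1, g2), clipped to >= 0
  k_init <- function(g1, g2) {
    X <- cbind(w * cos(th) * hg_phase(th, g1), w * cos(th) * hg_phase(th, g2))
    k <- tryCatch(qr.solve(X, y), error = function(e) c(1, 1))
    pmax(k, 1e-8)
  }

  starts <- expand.grid(g1 = c(0.6, 0.8, 0.9, 0.97), g2 = c(0.2, 0.6))
  lower <- c(0, 0, 0, 0)
  upper <- c(Inf, 0.9999, Inf, 0.9999)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    g1 <- starts$g1[i]; g2 <- starts$g2[i]
    k <- k_init(g1, g2)
    par0 <- c(k[1], g1, k[2], g2)
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    obj <- sum(resid_fn(res$par)^2)
    cand <- list(par = res$par, obj = obj)
    if (is.null(best) || obj < best$obj - 1e-14 ||
        (abs(obj - best$obj) <= 1e-14 && res$par[2] > best$par[2]))
      best <- cand
  }

  if (is.null(best))
    top_error("Two-lobe fit failed to converge from any starting point.",
              "tendonoptics_fit_failure")

  p <- best$par
  # order lobes: a negligible lobe (< 1e-6 of the other scale) goes second;
  # otherwise g1 >= g2
  if (p[1] < 1e-6 * p[3]) p <- p[c(3, 4, 1, 2)]
  else if (p[3] >= 1e-6 * p[1] && p[4] > p[2]) p <- p[c(3, 4, 1, 2)]
  fit <- double_hg_fit(K1 = p[1], g1 = min(p[2], 0.99989),
                       K2 = p[3], g2 = min(p[4], 0.99989),
                       residual = best$obj)
  fit <- effective_anisotropy(fit)
  fit$asymmetry <- f$asymmetry
  fit
}
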