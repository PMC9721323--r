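#' Scattering amplitude of a homogeneous sphere
#'
#' Amplitude (units: contrast x volume, nm^3) of a sphere of radius `R` and
#' scattering-length-density contrast `delta_rho`,
#' \deqn{F(q) = \Delta\rho \frac{4\pi}{3} R^3 \,
#'   \frac{3[\sin(qR) - qR\cos(qR)]}{(qR)^3}.}
#' At `q = 0` the analytic limit (particle volume times contrast) is returned.
#' Below `qR = 1e-2` a Taylor expansion is used to avoid catastrophic
#' cancellation.
#'
#' @param q Scattering vector (nm^-1), non-negative; vectorized.
#' @param R Sphere radius (nm), positive scalar.
#' @param delta_rho Scattering-length-density contrast (arbitrary units).
#' @return Numeric vector of amplitudes.
#' @export
sphere_form_amplitude <- function(q, R, delta_rho = 1) {
  if (!is.finite(R) || R <= 0) stop("R must be finite and > 0")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  V <- 4 * pi / 3 * R^3
  x <- q * R
  amp <- numeric(length(x))
  small <- x < 1e-2
  # Taylor: 3(sin x - x cos x)/x^3 = 1 - x^2/10 + x^4/280 - ...
  amp[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  xb <- x[!small]
  amp[!small] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  delta_rho * V * amp
}

#' Scattering intensity of a homogeneous sphere
#'
#' Convenience wrapper: `sphere_form_amplitude(q, R, delta_rho)^2`, the
#' single-particle intensity used as the kernel of size-distribution
#' integrals.
#'
#' @inheritParams sphere_form_amplitude
#' @return Numeric vector of per-particle intensities.
#' @export
sphere_intensity <- function(q, R, delta_rho = 1) {
  sphere_form_amplitude(q, R, delta_rho)^2
}

#' Debye-Anderson-Brumberger (DAB) intensity
#'
#' Scattering of a random two-phase medium with sharp interfaces and a single
#' correlation length `xi`:
#' \deqn{I(q) = I_0 / (1 + q^2 \xi^2)^2.}
#'
#' @param q Scattering vector (nm^-1), non-negative; vectorized.
#' @param xi Correlation length (nm), positive.
#' @param I0 Forward intensity (cm^-1), positive.
#' @return Numeric vector of intensities (cm^-1).
#' @export
dab_intensity <- function(q, xi, I0 = 1) {
  if (!is.finite(xi) || xi <= 0) stop("xi must be finite and > 0")
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be finite and > 0")
  if (any(!is.finite(q)) || any(q < 0)) stop("q must be finite and >= 0")
  I0 / (1 + q^2 * xi^2)^2
}

#' Projected correlation function of a sphere
#'
#' Correlation function of a homogeneous ball of radius `R`, projected along
#' one axis and normalized to 1 at the origin; the quantity measured by
#' SESANS and the real-space workhorse of the multiple-scattering formalism.
#' The ball autocorrelation is
#' \eqn{\gamma(u) = 1 - \frac{3u}{4R} + \frac{u^3}{16R^3}} for
#' \eqn{u \le 2R}, zero beyond; the projection
#' \eqn{G(z) \propto \int_0^\infty \gamma(\sqrt{z^2+s^2})\,ds} is evaluated in
#' closed form (the normalization constant is \eqn{3R/4}). `G(z) = 0` for
#' `z >= 2R`.
#'
#' @param r Distances (nm), non-negative; vectorized.
#' @param R Sphere radius (nm), positive scalar.
#' @return Numeric vector of correlations in \[0, 1\].
#' @export
sphere_projected_correlation <- function(r, R) {
  if (!is.finite(R) || R <= 0) stop("R must be finite and > 0")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and >= 0")
  z <- r
  out <- numeric(length(z))
  inside <- z < 2 * R
  zi <- z[inside]
  S <- sqrt(pmax(4 * R^2 - zi^2, 0))
  # antiderivatives of sqrt(z^2+s^2) and (z^2+s^2)^(3/2) on [0, S], using
  # sqrt(z^2+S^2) = 2R on the support boundary; L := ln((S+2R)/z)
  L <- ifelse(zi > 0, log((S + 2 * R) / ifelse(zi > 0, zi, 1)), 0)
  A1 <- (2 * R * S + zi^2 * L) / 2
  A3 <- 2 * R^3 * S + (3 / 8) * (2 * R * S * zi^2 + zi^4 * L)
  proj <- S - 3 / (4 * R) * A1 + A3 / (16 * R^3)
  out[inside] <- proj / (3 * R / 4)
  out[z == 0] <- 1
  pmin(pmax(out, 0), 1)
}

#' Projected correlation function of the DAB model
#'
#' For an exponential correlation \eqn{\gamma(u) = e^{-u/\xi}} the projection
#' along one axis gives \eqn{G(z) = (z/\xi) K_1(z/\xi)}, with
#' \eqn{K_1} the modified Bessel function of the second kind. `G(0) = 1`
#' (analytic limit).
#'
#' @param r Distances (nm), non-negative; vectorized.
#' @param xi Correlation length (nm), positive.
#' @return Numeric vector of correlations in \[0, 1\].
#' @export
dab_projected_correlation <- function(r, xi) {
  if (!is.finite(xi) || xi <= 0) stop("xi must be finite and > 0")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and >= 0")
  x <- r / xi
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * besselK(x[pos], 1)
  out[!pos] <- 1
  # x*K1(x) -> 1 as x -> 0; besselK underflows to 0 for x > ~700, fine
  out[!is.finite(out)] <- 0
  out
}

#' Form-factor model registry
#'
#' Maps model names used by the command-line interface to evaluator
#' constructors. `"sphere"` takes parameters `R` and `delta_rho`; `"dab"`
#' takes `xi` and `I0`.
#'
#' @param name One of `"sphere"`, `"dab"`.
#' @return A function `f(q)` evaluating the model intensity.
#' @param params Named list of model parameters.
#' @export
model_registry <- function(name, params = list()) {
  switch(match.arg(name, c("sphere", "dab")),
    sphere = {
      R <- params$R %||% 10
      drho <- params$delta_rho %||% 1
      function(q) sphere_intensity(q, R, drho)
    },
    dab = {
      xi <- params$xi %||% 10
      I0 <- params$I0 %||% 1
      function(q) dab_intensity(q, xi, I0)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
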