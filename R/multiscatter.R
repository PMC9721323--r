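#' Multiple-scattering experimental parameters
#'
#' Bundles the scale and instrument parameters of the multiple-scattering
#' model: the total scattering cross section per sample volume
#' \eqn{\Sigma_t} (cm^-1), the sample thickness `t` (cm) and the wavelength
#' \eqn{\lambda} (nm). Their product \eqn{\tau = \Sigma_t t} is the optical
#' depth, the mean number of scattering events.
#'
#' @param sigma_t Total scattering cross section per volume (cm^-1), > 0.
#' @param t Sample thickness (cm), > 0.
#' @param lam Wavelength (nm), > 0.
#' @return An object of class `multiscatter_params` with derived field `tau`.
#' @export
multiscatter_params <- function(sigma_t, t, lam) {
  stopifnot(is.finite(sigma_t), sigma_t > 0,
            is.finite(t), t > 0, is.finite(lam), lam > 0)
  structure(list(sigma_t = sigma_t, t = t, lam = lam, tau = sigma_t * t),
            class = "multiscatter_params")
}

# normalized projected correlation G(r) (G(0) = 1) for the supported models,
# plus an r beyond which G is negligible/zero
.projected_correlation <- function(model, params) {
  switch(model,
    sphere_mono = {
      R <- params$R
      stopifnot(is.finite(R), R > 0)
      list(G = function(r) sphere_projected_correlation(r, R), r_sup = 2 * R)
    },
    sphere_lognormal = {
      m <- params$median; s <- params$shape
      stopifnot(m > 0, s > 0)
      # mixture of single-sphere projections; each sphere enters with weight
      # proportional to its forward projection Drho^2 V(R) * (3R/4) ~ R^4
      gl <- .gl_nodes(101L, 1e-6, 1 - 1e-6)
      Rn <- stats::qlnorm(gl$x, log(m), s)
      w <- gl$w * Rn^4
      w <- w / sum(w)
      Rmax <- max(Rn)
      list(G = function(r) {
        out <- numeric(length(r))
        for (i in seq_along(Rn))
          out <- out + w[i] * sphere_projected_correlation(r, Rn[i])
        out
      }, r_sup = 2 * Rmax)
    },
    dab = {
      xi <- params$xi
      stopifnot(is.finite(xi), xi > 0)
      # (r/xi) K1(r/xi) < 1e-16 beyond ~ 40 xi
      list(G = function(r) dab_projected_correlation(r, xi), r_sup = 45 * xi)
    },
    stop("model '", model, "' has no analytic projected correlation")
  )
}

#' Multiple-scattering intensity
#'
#' Computes the measured (multiply scattered) cross section from the
#' single-scattering description of a model with an analytic projected
#' correlation function \eqn{G(r)} (\eqn{G(0) = 1}). With optical depth
#' \eqn{\tau = \Sigma_t t}, the real-space multiple-scattering kernel is
#' \deqn{i_m(r) \propto e^{-\tau}\left(e^{\tau G(r)} - 1\right),}
#' and the intensity is its inverse Hankel transform
#' \deqn{\left(\frac{d\Sigma}{d\Omega}\right)_m(q) = \frac{2\pi}{\lambda^2 t}
#'   \int_0^\infty e^{-\tau}\left(e^{\tau G(r)} - 1\right) J_0(qr)\, r\, dr.}
#' As \eqn{\tau \to 0} this converges to the single-scattering curve whose
#' total cross section is \eqn{\Sigma_t}.
#'
#' @param model One of `"sphere_mono"` (parameter `R`), `"sphere_lognormal"`
#'   (`median`, `shape`) or `"dab"` (`xi`).
#' @param model_params Named list of model parameters.
#' @param msp A [multiscatter_params()] object.
#' @param q Output scattering-vector grid (nm^-1).
#' @return A [sas_curve()] (cm^-1).
#' @export
multiple_scattering_intensity <- function(model, model_params, msp, q) {
  stopifnot(inherits(msp, "multiscatter_params"))
  tau <- msp$tau
  if (tau > 50) stop("optical depth tau = ", signif(tau, 4),
                     " > 50: kernel would overflow")
  pc <- .projected_correlation(model, model_params)
  kern <- function(r) exp(-tau) * expm1(tau * pc$G(r))
  I <- .hankel_fn(kern, q, upper = pc$r_sup)
  sas_curve(q, 2 * pi / (msp$lam^2 * msp$t) * I)
}

#' Single-scattering intensity with a given total cross section
#'
#' The \eqn{\tau \to 0} limit of [multiple_scattering_intensity()]: the
#' single-scattering curve of the model normalized so its total scattering
#' cross section per volume equals `msp$sigma_t`,
#' \eqn{I_1(q) = \Sigma_t (2\pi/\lambda^2) \int_0^\infty G(r) J_0(qr) r\,dr}.
#'
#' @inheritParams multiple_scattering_intensity
#' @return A [sas_curve()] (cm^-1).
#' @export
single_scattering_intensity <- function(model, model_params, msp, q) {
  stopifnot(inherits(msp, "multiscatter_params"))
  pc <- .projected_correlation(model, model_params)
  I <- .hankel_fn(pc$G, q, upper = pc$r_sup)
  sas_curve(q, msp$sigma_t * 2 * pi / msp$lam^2 * I)
}

#' Total scattering cross section per volume
#'
#' \deqn{\Sigma_t = \frac{\lambda^2}{2\pi} \int_0^\infty
#'   \frac{d\Sigma}{d\Omega}(q)\, q\, dq,}
#' with units: `q` in nm^-1, intensity in cm^-1, wavelength in nm, giving
#' \eqn{\Sigma_t} in cm^-1. For a sampled curve the integral uses the
#' trapezoidal rule on the grid plus an analytic power-law tail fitted to the
#' top quarter of the grid; a tail decaying like \eqn{q^{-2}} or slower
#' raises a divergence error. A function input is integrated adaptively.
#'
#' @param curve A [sas_curve()] or a function `I(q)`.
#' @param lam Wavelength (nm).
#' @return Scalar \eqn{\Sigma_t} (cm^-1).
#' @export
total_cross_section <- function(curve, lam) {
  stopifnot(is.finite(lam), lam > 0)
  if (is.function(curve)) {
    val <- stats::integrate(function(t) curve(t) * t, 0, Inf,
                            rel.tol = 1e-10, subdivisions = 500L)$value
    return(lam^2 / (2 * pi) * val)
  }
  stopifnot(.is_curve(curve))
  q <- curve$q; I <- curve$intensity
  core <- pracma::trapz(q, I * q)
  ev <- .curve_evaluator(curve)
  qmax <- max(q); Imax <- I[length(I)]
  tail <- if (Imax > 0 && is.finite(ev$slope)) {
    if (ev$slope >= -2)
      stop("intensity tail decays like q^", sprintf("%.2f", ev$slope),
           ": total cross section diverges")
    # int_qmax^inf Imax (q/qmax)^p q dq = Imax qmax^2 / (-(p+2))
    Imax * qmax^2 / (-(ev$slope + 2))
  } else 0
  lam^2 / (2 * pi) * (core + tail)
}
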