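#' Real-space grid for the OZ solver
#'
#' Uniform grid with `n` points (a power of two) and spacing `dr` (nm). The
#' implied reciprocal spacing is \eqn{\Delta k = \pi/(n\,\Delta r)}. The
#' default, n = 2^14 points at \eqn{\Delta r = \sigma/500}, resolves both
#' the core discontinuity and the long-range tail of typical potentials.
#'
#' @param n Number of points, a power of two.
#' @param dr Spacing (nm), > 0.
#' @return An object of class `oz_grid`.
#' @export
oz_grid <- function(n = 2^14, dr) {
  if (n < 8 || bitwAnd(n, n - 1L) != 0) stop("n must be a power of 2")
  stopifnot(is.finite(dr), dr > 0)
  structure(list(n = as.integer(n), dr = dr, dk = pi / (n * dr)),
            class = "oz_grid")
}

#' Pair potentials
#'
#' Constructors for the spherically symmetric pair potentials understood by
#' the solver; energies are in units of kT.
#' `potential_hard_sphere`: infinite inside the diameter `sigma`, zero
#' outside. `potential_piecewise`: hard core plus constant shells, given as
#' steps `(range, E)` where `range` is the outer shell edge in multiples of
#' `sigma` (strictly increasing, > 1) and `E` the shell energy/kT.
#' `potential_two_yukawa`: hard core plus
#' \eqn{u(r)/kT = -K_1 e^{-Z_1 (r/\sigma - 1)}/(r/\sigma)
#'               - K_2 e^{-Z_2 (r/\sigma - 1)}/(r/\sigma)};
#' positive `K` means attraction. `potential_lennard_jones`:
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, no hard core.
#'
#' @param sigma Hard-core diameter / length parameter (nm), > 0.
#' @return An object of class `pair_potential`.
#' @export
potential_hard_sphere <- function(sigma) {
  stopifnot(sigma > 0)
  structure(list(kind = "hard_sphere", sigma = sigma, has_core = TRUE),
            class = "pair_potential")
}

#' @rdname potential_hard_sphere
#' @param ranges Outer shell edges as multiples of `sigma`, strictly
#'   increasing, all > 1.
#' @param E Shell energies (kT), same length as `ranges`.
#' @export
potential_piecewise <- function(sigma, ranges, E) {
  stopifnot(sigma > 0, length(ranges) == length(E), all(ranges > 1),
            all(diff(ranges) > 0), all(is.finite(E)))
  structure(list(kind = "piecewise_constant", sigma = sigma,
                 ranges = ranges, E = E, has_core = TRUE),
            class = "pair_potential")
}

#' @rdname potential_hard_sphere
#' @param K1,K2 Yukawa amplitudes (kT); positive = attraction.
#' @param Z1,Z2 Inverse ranges (dimensionless), > 0.
#' @export
potential_two_yukawa <- function(sigma, K1, Z1, K2 = 0, Z2 = 1) {
  stopifnot(sigma > 0, Z1 > 0, Z2 > 0, is.finite(K1), is.finite(K2))
  structure(list(kind = "two_yukawa", sigma = sigma, K1 = K1, Z1 = Z1,
                 K2 = K2, Z2 = Z2, has_core = TRUE),
            class = "pair_potential")
}

#' @rdname potential_hard_sphere
#' @param eps Well depth (kT), > 0.
#' @export
potential_lennard_jones <- function(sigma, eps) {
  stopifnot(sigma > 0, eps > 0)
  structure(list(kind = "lennard_jones", sigma = sigma, eps = eps,
                 has_core = FALSE),
            class = "pair_potential")
}

#' Evaluate a pair potential
#'
#' @param p A `pair_potential`.
#' @param r Distances (nm), strictly positive.
#' @return `u(r)/kT`; `Inf` inside a hard core.
#' @export
potential_eval <- function(p, r) {
  stopifnot(inherits(p, "pair_potential"))
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be finite and > 0")
  s <- p$sigma
  switch(p$kind,
    hard_sphere = ifelse(r < s, Inf, 0),
    piecewise_constant = {
      u <- numeric(length(r))
      u[r < s] <- Inf
      edges <- c(1, p$ranges) * s
      for (i in seq_along(p$E))
        u[r >= edges[i] & r < edges[i + 1]] <- p$E[i]
      # contact point r = sigma belongs to the first shell
      u
    },
    two_yukawa = {
      x <- r / s
      u <- -p$K1 * exp(-p$Z1 * (x - 1)) / x - p$K2 * exp(-p$Z2 * (x - 1)) / x
      u[r < s] <- Inf
      u
    },
    lennard_jones = 4 * p$eps * ((s / r)^12 - (s / r)^6)
  )
}

#' Apply a closure relation
#'
#' Computes the direct correlation function `c(r)` from the potential and
#' the indirect correlation \eqn{\gamma = h - c}. Outside the core:
#' Percus-Yevick \eqn{c = (e^{-u} - 1)(1 + \gamma)}; hypernetted chain
#' \eqn{c = e^{-u + \gamma} - 1 - \gamma}; MSA \eqn{c = -u}; modified MSA
#' \eqn{c = e^{-u} - 1}. Inside a hard core the exact condition `g = 0` is
#' enforced via \eqn{c = -1 - \gamma} for every closure.
#'
#' @param closure One of `"PY"`, `"HNC"`, `"MSA"`, `"mMSA"`.
#' @param u Potential array `u(r)/kT` (may contain `Inf` inside the core).
#' @param gamma Indirect correlation array, same length.
#' @param core_mask Logical array marking hard-core points.
#' @return Direct correlation array `c(r)`.
#' @export
closure_apply <- function(closure, u, gamma, core_mask = is.infinite(u)) {
  closure <- match.arg(closure, c("PY", "HNC", "MSA", "mMSA"))
  stopifnot(length(u) == length(gamma))
  uo <- ifelse(core_mask, 0, u)  # masked: +Inf never enters exponentials
  cr <- switch(closure,
    PY = (exp(-uo) - 1) * (1 + gamma),
    HNC = {
      ex <- -uo + gamma
      if (any(ex[!core_mask] > 700))
        stop("overflow in exp(-u + gamma); use stronger mixing")
      exp(ex) - 1 - gamma
    },
    MSA = -uo,
    mMSA = exp(-uo) - 1
  )
  cr[core_mask] <- -1 - gamma[core_mask]
  cr
}

#' Radial Fourier transform on the OZ grid
#'
#' Three-dimensional radial Fourier transform
#' \eqn{\hat f(k) = (4\pi/k) \int_0^\infty r f(r) \sin(kr)\, dr} realized as
#' a discrete sine transform (via FFT) on the uniform grid
#' \eqn{r_j = j\,\Delta r}, \eqn{k_m = m\,\Delta k}; the inverse carries the
#' reciprocal normalization \eqn{1/(2\pi^2)}. Input and output are arrays of
#' length `n - 1` (the interior grid points).
#'
#' @param f Real-space (or reciprocal, when `inverse`) array of length
#'   `grid$n - 1`.
#' @param grid An [oz_grid()].
#' @param inverse Logical; apply the inverse transform.
#' @return Transformed array of length `grid$n - 1`.
#' @export
radial_fourier <- function(f, grid, inverse = FALSE) {
  stopifnot(inherits(grid, "oz_grid"))
  N <- grid$n
  if (length(f) != N - 1L) stop("f must have length n - 1")
  m <- seq_len(N - 1L)
  r <- m * grid$dr
  k <- m * grid$dk
  # DST-I via odd extension: S_m = sum_j w_j sin(pi j m / N)
  w <- if (!inverse) f * r else f * k
  z <- c(0, w, 0, -rev(w))
  S <- -Im(stats::fft(z))[2:N] / 2
  if (!inverse) 4 * pi * grid$dr * S / k
  else grid$dk * S / (2 * pi^2 * r)
}

#' Analytic Percus-Yevick hard-sphere structure factor
#'
#' Closed-form structure factor of the hard-sphere fluid in the
#' Percus-Yevick approximation (Wertheim solution): the direct correlation
#' inside the core is the cubic
#' \eqn{c(r) = -(\alpha + \beta (r/\sigma) + \delta (r/\sigma)^3)} with
#' \eqn{\alpha = (1+2\eta)^2/(1-\eta)^4},
#' \eqn{\beta = -6\eta(1+\eta/2)^2/(1-\eta)^4},
#' \eqn{\delta = \eta\alpha/2}, and
#' \eqn{S(q) = 1/(1 - \rho \hat c(q))} with \eqn{\hat c} evaluated
#' analytically. Small-`q` evaluation switches to series expansions for
#' numerical stability; \eqn{S(0) = (1-\eta)^4/(1+2\eta)^2}.
#'
#' @param q Scattering vectors (nm^-1), >= 0.
#' @param eta Volume fraction in (0, 0.74).
#' @param sigma Hard-core diameter (nm).
#' @return Structure-factor values.
#' @export
hs_py_analytic <- function(q, eta, sigma = 1) {
  stopifnot(eta > 0, eta < 0.74, sigma > 0)
  x <- q * sigma
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  de <- eta * al / 2
  T2 <- T3 <- T5 <- numeric(length(x))
  small <- x < 0.1
  xs <- x[small]
  T2[small] <- 1 / 3 - xs^2 / 30 + xs^4 / 840
  T3[small] <- 1 / 4 - xs^2 / 36 + xs^4 / 960
  T5[small] <- 1 / 6 - xs^2 / 48 + xs^4 / 1200
  xb <- x[!small]
  T2[!small] <- (sin(xb) - xb * cos(xb)) / xb^3
  T3[!small] <- (2 * xb * sin(xb) - (xb^2 - 2) * cos(xb) - 2) / xb^4
  T5[!small] <- ((4 * xb^3 - 24 * xb) * sin(xb) -
                   (xb^4 - 12 * xb^2 + 24) * cos(xb) + 24) / xb^6
  rho_chat <- -24 * eta * (al * T2 + be * T3 + de * T5)
  1 / (1 - rho_chat)
}

#' Numerical Ornstein-Zernike solver
#'
#' Solves the OZ equation \eqn{h = c + \rho\, c * h} for a spherically
#' symmetric pair potential under a chosen closure, by Picard iteration on
#' the indirect correlation \eqn{\gamma = h - c}: given \eqn{\gamma},
#' compute `c` from the closure, transform, apply
#' \eqn{\hat\gamma = \rho \hat c^2 / (1 - \rho \hat c)}, transform back,
#' and mix \eqn{\gamma \leftarrow (1-\alpha)\gamma + \alpha\gamma_{OZ}}.
#' Density and volume fraction are related by \eqn{\rho = 6\eta/(\pi\sigma^3)}
#' (for Lennard-Jones, `sigma` is the length parameter and `eta` is
#' interpreted through the same formula).
#'
#' The MSA closure requires a potential with a hard core; combining it with
#' the Lennard-Jones potential raises an error (its \eqn{c = -u} tail is not
#' integrable against a soft \eqn{r^{-12}} core).
#'
#' @param potential A `pair_potential`.
#' @param closure `"PY"`, `"HNC"`, `"MSA"` or `"mMSA"`.
#' @param eta Volume fraction in (0, 0.74).
#' @param grid An [oz_grid()]; default n = 2^14, dr = sigma/500.
#' @param mixing Picard mixing parameter in (0, 1\].
#' @param tol Convergence tolerance on `max|gamma_new - gamma_old|`
#'   (pre-mixing residual).
#' @param max_iter Iteration cap.
#' @return An object of class `oz_solution` with fields `r`, `c_r`, `h_r`,
#'   `g_r`, `q`, `S_q`, `eta`, `converged`, `iterations`, `residual`.
#' @export
oz_solve <- function(potential, closure, eta, grid = NULL, mixing = 0.2,
                     tol = 1e-8, max_iter = 1e5L) {
  stopifnot(inherits(potential, "pair_potential"), eta > 0, eta < 0.74,
            mixing > 0, mixing <= 1)
  closure <- match.arg(closure, c("PY", "HNC", "MSA", "mMSA"))
  if (closure == "MSA" && !isTRUE(potential$has_core))
    stop("MSA closure requires a potential with a hard core")
  sigma <- potential$sigma
  if (is.null(grid)) grid <- oz_grid(2^14, sigma / 500)
  N <- grid$n
  r <- seq_len(N - 1L) * grid$dr
  k <- seq_len(N - 1L) * grid$dk
  u <- potential_eval(potential, r)
  core <- if (isTRUE(potential$has_core)) r < sigma else is.infinite(u)
  # grid point sitting on the core edge: c(r) jumps there; use the mean of
  # the one-sided limits (trapezoidal treatment of the discontinuity)
  jedge <- if (isTRUE(potential$has_core)) {
    je <- which.min(abs(r - sigma))
    if (abs(r[je] - sigma) < grid$dr / 2 + 1e-12) je else NA_integer_
  } else NA_integer_
  close_edge <- function(gamma) {
    cr <- closure_apply(closure, u, gamma, core)
    if (!is.na(jedge))
      cr[jedge] <- 0.5 * (-1 - gamma[jedge]) + 0.5 * cr[jedge]
    cr
  }
  rho <- 6 * eta / (pi * sigma^3)
  gamma <- numeric(N - 1L)
  converged <- FALSE
  resid <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cr <- close_edge(gamma)
    chat <- radial_fourier(cr, grid)
    denom <- 1 - rho * chat
    if (any(denom <= 0))
      stop("1 - rho*c_hat(k) <= 0: spinodal/instability region, no physical solution")
    ghat <- rho * chat^2 / denom
    gamma_oz <- radial_fourier(ghat, grid, inverse = TRUE)
    resid <- max(abs(gamma_oz - gamma))
    gamma <- (1 - mixing) * gamma + mixing * gamma_oz
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("OZ solver did not converge in %d iterations (residual %.3e)",
                 iter, resid))
  cr <- close_edge(gamma)
  chat <- radial_fourier(cr, grid)
  ghat <- rho * chat^2 / (1 - rho * chat)
  h <- gamma + cr
  S <- 1 + rho * (chat + ghat)
  structure(list(r = r, c_r = cr, h_r = h, g_r = 1 + h, q = k, S_q = S,
                 eta = eta, rho = rho, sigma = sigma, closure = closure,
                 converged = converged, iterations = iter, residual = resid,
                 grid = grid),
            class = "oz_solution")
}

#' @export
print.oz_solution <- function(x, ...) {
  cat(sprintf("<oz_solution> %s, eta = %g, %d iterations, residual %.2e\n",
              x$closure, x$eta, x$iterations, x$residual))
  invisible(x)
}

#' Polydisperse intensity with a structure factor
#'
#' Combines a size distribution of sphere-like scatterers with a structure
#' factor using either the decoupling approximation,
#' \deqn{I(q) = n\,[\langle F^2\rangle + \langle F\rangle^2 (S(q) - 1)],}
#' or the local monodisperse approximation,
#' \deqn{I(q) = n \int p(R)\, F^2(q, R)\, S(q; \sigma(R))\, dR,}
#' where the local structure factor is evaluated with the hard-core diameter
#' mapped from the radius as \eqn{\sigma(R) =} `sigma_factor * R`.
#'
#' @param amplitude Function `F(q, R)` (scattering amplitude), vectorized in
#'   `q`.
#' @param dist A `size_distribution`.
#' @param q Scattering-vector grid.
#' @param S_q Structure factor on `q` (vector) — required for
#'   `"decoupling"`.
#' @param S_fun Function `S(q, sigma)` — required for
#'   `"local_monodisperse"`.
#' @param scheme `"decoupling"` or `"local_monodisperse"`.
#' @param n_density Number density prefactor.
#' @param sigma_factor Radius-to-diameter mapping for the local scheme.
#' @return A [sas_curve()].
#' @export
effective_intensity <- function(amplitude, dist, q, S_q = NULL, S_fun = NULL,
                                scheme = c("decoupling", "local_monodisperse"),
                                n_density = 1, sigma_factor = 2) {
  scheme <- match.arg(scheme)
  if (scheme == "decoupling") {
    if (is.null(S_q)) stop("decoupling approximation needs S_q on the q grid")
    F2 <- integrate_over_distribution(function(q, x) amplitude(q, x)^2, dist, q)
    F1 <- integrate_over_distribution(amplitude, dist, q)
    I <- n_density * (F2$intensity + F1$intensity^2 * (S_q - 1))
  } else {
    if (is.null(S_fun)) stop("local monodisperse approximation needs S_fun(q, sigma)")
    I <- integrate_over_distribution(
      function(q, x) amplitude(q, x)^2 * S_fun(q, sigma_factor * x),
      dist, q)$intensity * n_density
  }
  sas_curve(q, I)
}
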