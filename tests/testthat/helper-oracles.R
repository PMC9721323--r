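# Shared oracles and fixtures, computed in code at test time.

# ball autocorrelation, support [0, 2R] — projection-integral oracle input
ball_autocorrelation <- function(u, R) {
  ifelse(u <= 2 * R, 1 - 3 * u / (4 * R) + u^3 / (16 * R^3), 0)
}

# normative projection-integral oracle for projected correlations
project_gamma <- function(gamma_fn, z, rel.tol = 1e-10) {
  raw <- vapply(z, function(zz)
    stats::integrate(function(s) gamma_fn(sqrt(zz^2 + s^2)), 0, Inf,
                     rel.tol = rel.tol)$value, numeric(1))
  raw / stats::integrate(gamma_fn, 0, Inf, rel.tol = rel.tol)$value
}

# brute-force 3D radial Fourier transform of the unit-density ball
ball_ft_oracle <- function(q, R) {
  stats::integrate(function(r) 4 * pi * r^2 * sin(q * r) / (q * r), 0, R,
                   rel.tol = 1e-12)$value
}

# grid-level two-peak finder: local maxima, largest two separated in log-size
find_two_peaks <- function(x, R, min_sep = 0.3) {
  x <- pmax(x, 0)
  n <- length(x)
  loc <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  loc <- loc[order(x[loc], decreasing = TRUE)]
  sel <- integer(0)
  for (i in loc) {
    if (all(abs(log(R[i] / R[sel])) > min_sep)) sel <- c(sel, i)
    if (length(sel) == 2L) break
  }
  sort(R[sel])
}

# grid argmax of the true volume-weighted density near each nominal mode
true_modes_on_grid <- function(dist, R, nominal) {
  dv <- dist_pdf(dist, R) * R^3
  vapply(nominal, function(m)
    R[which.max(ifelse(abs(log(R / m)) < 0.5, dv, 0))], numeric(1))
}

# default benchmark: bimodal lognormal spheres, 1% noise (study conditions)
benchmark_curve <- function(seed = 1L) {
  simulate_curve(synthetic_spec(), seed = seed)
}

benchmark_kernel <- function(curve, n_bins = 100L) {
  R <- default_size_grid(curve$q, n_bins)
  list(R = R, kernel = build_kernel(curve$q, R, weighting = "volume"))
}

# truncated multiple-scattering series oracle: sum_n e^-tau tau^n/n! H[G^n]
msas_series_oracle <- function(G, tau, lam, t, q, r_sup, n_terms = 25L) {
  acc <- numeric(length(q))
  for (n in seq_len(n_terms)) {
    Hn <- vapply(q, function(qq) saskit:::.hankel_point(
      function(r) G(r)^n, qq, upper = r_sup), numeric(1))
    acc <- acc + exp(-tau) * tau^n / factorial(n) * Hn
  }
  2 * pi / (lam^2 * t) * acc
}
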