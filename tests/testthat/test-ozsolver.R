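test_that("potentials evaluate to their defining piecewise forms", {
  hs <- potential_hard_sphere(2)
  expect_equal(potential_eval(hs, c(1, 3)), c(Inf, 0))
  expect_equal(potential_eval(hs, 1.5 * 2), 0)
  ty <- potential_two_yukawa(1, K1 = 1.5, Z1 = 10, K2 = 0.5, Z2 = 2)
  expect_equal(potential_eval(ty, 1 + 1e-14), -(1.5 + 0.5), tolerance = 1e-10)
  pw <- potential_piecewise(1, c(1.5, 2), c(-1, 0.5))
  expect_equal(potential_eval(pw, c(1.2, 1.8, 2.5)), c(-1, 0.5, 0))
  lj <- potential_lennard_jones(1, 1)
  expect_equal(potential_eval(lj, 1), 0)
  expect_equal(potential_eval(lj, 2^(1 / 6)), -1)   # well minimum
  expect_error(potential_eval(hs, c(-1, 1)), "r must be")
})

test_that("closures reduce to the ideal gas and enforce the core condition", {
  n <- 5
  z <- rep(0, n)
  for (cl in c("PY", "HNC", "MSA", "mMSA"))
    expect_equal(closure_apply(cl, z, z, rep(FALSE, n)), z)
  # core condition c = -1 - gamma
  u <- c(Inf, Inf, 0, 0)
  g <- c(0.3, 0.1, 0.2, 0)
  expect_equal(closure_apply("PY", u, g)[1:2], c(-1.3, -1.1))
  # PY and HNC agree to first order in a small potential
  us <- seq(-0.01, 0.01, length.out = 21)
  expect_lt(max(abs(closure_apply("PY", us, rep(0, 21), rep(FALSE, 21)) -
                    closure_apply("HNC", us, rep(0, 21), rep(FALSE, 21)))), 1e-4)
})

test_that("radial Fourier transform has an exact inverse and matches closed forms", {
  g <- oz_grid(2^12, 0.01)
  r <- seq_len(g$n - 1) * g$dr
  k <- seq_len(g$n - 1) * g$dk
  f <- exp(-r) * cos(0.3 * r)
  expect_lt(sqrt(mean((radial_fourier(radial_fourier(f, g), g, inverse = TRUE) - f)^2)),
            1e-10)
  # screened-Coulomb pair e^-r/r <-> 4 pi/(1+k^2); discretization error ~ (dr k)^2/12
  fh <- radial_fourier(exp(-r) / r, g)
  sel <- k * g$dr <= 0.03
  ref <- 4 * pi / (1 + k[sel]^2)
  expect_lt(max(abs(fh[sel] - ref) / ref), 1e-4)
  # quadratic error decay in dr at fixed k
  g2 <- oz_grid(2^13, 0.005)
  k2 <- seq_len(g2$n - 1) * g2$dk
  fh2 <- radial_fourier(exp(-(seq_len(g2$n - 1) * g2$dr)) / (seq_len(g2$n - 1) * g2$dr), g2)
  i1 <- which.min(abs(k - 2)); i2 <- which.min(abs(k2 - k[i1]))
  e1 <- abs(fh[i1] - 4 * pi / (1 + k[i1]^2))
  e2 <- abs(fh2[i2] - 4 * pi / (1 + k2[i2]^2))
  expect_lt(e2, e1 / 2)
  # unit ball indicator: f_hat(k -> 0) tends to the ball volume
  # half-weight at the jump point (trapezoidal convention for the step)
  ball <- as.numeric(r < 1 - 1e-9) + 0.5 * (abs(r - 1) < 1e-9)
  bh <- radial_fourier(ball, g)
  expect_equal(bh[1], 4 * pi / 3, tolerance = 1e-3)
})

test_that("analytic PY hard-sphere structure factor has the right limits", {
  eta <- 0.3
  expect_equal(hs_py_analytic(1e-10, eta), (1 - eta)^4 / (1 + 2 * eta)^2,
               tolerance = 1e-8)
  expect_equal(hs_py_analytic(200, eta), 1, tolerance = 1e-3)
  expect_equal(hs_py_analytic(3, 1e-6), 1, tolerance = 1e-5)
  # against direct quadrature of the Wertheim direct correlation
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  de <- eta * al / 2
  rho <- 6 * eta / pi
  for (qq in c(0.2, 2, 7.2, 30)) {
    chat <- 4 * pi / qq * stats::integrate(function(r)
      -(al + be * r + de * r^3) * r * sin(qq * r), 0, 1, rel.tol = 1e-12)$value
    expect_equal(hs_py_analytic(qq, eta), 1 / (1 - rho * chat), tolerance = 1e-8)
  }
  # series branch agrees with quadrature just below the switch point
  qq <- 0.0999
  chat <- 4 * pi / qq * stats::integrate(function(r)
    -(al + be * r + de * r^3) * r * sin(qq * r), 0, 1, rel.tol = 1e-12)$value
  expect_equal(hs_py_analytic(qq, eta), 1 / (1 - rho * chat), tolerance = 1e-8)
})

test_that("numerical PY hard-sphere solution matches the Wertheim closed form", {
  # moderate grid here; the full reference grid runs in the acceptance suite
  sol <- oz_solve(potential_hard_sphere(1), "PY", eta = 0.3,
                  grid = oz_grid(2^13, 1 / 250))
  sel <- sol$q >= 0.2 & sol$q <= 40
  expect_lt(max(abs(sol$S_q[sel] - hs_py_analytic(sol$q[sel], 0.3))), 5e-3)
  expect_true(sol$converged)
})

test_that("solutions are physical: positive S(q), g(r) >= 0, core exclusion, correct limits", {
  sol <- oz_solve(potential_two_yukawa(1, K1 = 0.5, Z1 = 8, K2 = -0.1, Z2 = 1),
                  "HNC", eta = 0.2, grid = oz_grid(2^12, 1 / 200))
  expect_true(all(sol$S_q > 0))
  expect_true(all(sol$g_r >= -1e-8))
  expect_true(all(abs(sol$g_r[sol$r < 1 - sol$grid$dr]) < 1e-10))
  ntail <- sol$grid$n %/% 4
  expect_lt(max(abs(utils::tail(sol$g_r, ntail) - 1)), 1e-3)
  expect_lt(abs(utils::tail(sol$S_q, 1) - 1), 1e-2)
})

test_that("MSA with vanishing Yukawa tails reproduces the PY hard-sphere solution", {
  g <- oz_grid(2^12, 1 / 200)
  s1 <- oz_solve(potential_two_yukawa(1, K1 = 0, Z1 = 10, K2 = 0, Z2 = 2), "MSA",
                 0.3, grid = g)
  s2 <- oz_solve(potential_hard_sphere(1), "PY", 0.3, grid = g)
  expect_lt(max(abs(s1$S_q - s2$S_q)), 1e-6)
})

test_that("MSA refuses potentials without a hard core", {
  expect_error(oz_solve(potential_lennard_jones(1, 0.1), "MSA", 0.2),
               "hard core")
})

test_that("ideal-gas limit gives S = 1", {
  sol <- oz_solve(potential_hard_sphere(1), "PY", eta = 1e-8,
                  grid = oz_grid(2^10, 1 / 50))
  expect_lt(max(abs(sol$S_q - 1)), 1e-6)
})

test_that("grid refinement changes the converged solution by little", {
  # same extent n*dr, so the reciprocal grids coincide on the coarse range
  s1 <- oz_solve(potential_hard_sphere(1), "PY", 0.2, grid = oz_grid(2^13, 1 / 250))
  s2 <- oz_solve(potential_hard_sphere(1), "PY", 0.2, grid = oz_grid(2^14, 1 / 500))
  idx <- seq_along(s1$q)
  expect_equal(s1$q, s2$q[idx], tolerance = 1e-12)
  sel <- s1$q <= 40
  expect_lt(max(abs(s1$S_q[sel] - s2$S_q[idx][sel])), 1e-4)
})

test_that("short-range attraction with weak long-range repulsion produces a cluster peak", {
  sy <- oz_solve(potential_two_yukawa(1, K1 = 6, Z1 = 10, K2 = -0.3, Z2 = 0.5),
                 "MSA", eta = 0.15, grid = oz_grid(2^13, 1 / 250), mixing = 0.1)
  hs <- oz_solve(potential_hard_sphere(1), "PY", eta = 0.15,
                 grid = oz_grid(2^13, 1 / 250))
  q_primary <- hs$q[which.max(hs$S_q * (hs$q > 2))]
  S <- sy$S_q; qv <- sy$q
  loc <- which(S[2:(length(S) - 1)] > S[1:(length(S) - 2)] &
                 S[2:(length(S) - 1)] > S[3:length(S)]) + 1L
  loc <- loc[qv[loc] > 0.1 & qv[loc] < q_primary]
  expect_gt(length(loc), 0)
})

test_that("polydispersity approximations reduce correctly in degenerate limits", {
  q <- exp(seq(log(0.05), log(1), length.out = 20))
  amp <- function(q, R) sphere_form_amplitude(q, R)
  Sq <- hs_py_analytic(q, 0.2, sigma = 20)
  mono <- dist_delta(10)
  dec <- effective_intensity(amp, mono, q, S_q = Sq, scheme = "decoupling")
  expect_equal(dec$intensity, sphere_intensity(q, 10) * Sq, tolerance = 1e-10)
  lmono <- effective_intensity(amp, mono, q, S_fun = function(q, s)
    hs_py_analytic(q, 0.2, s), scheme = "local_monodisperse")
  expect_equal(lmono$intensity, sphere_intensity(q, 10) * Sq, tolerance = 1e-10)
  # S = 1 recovers the pure polydisperse form factor
  d <- dist_lognormal(10, 0.1)
  ff <- integrate_over_distribution(function(q, x) sphere_intensity(q, x), d, q)
  dec1 <- effective_intensity(amp, d, q, S_q = rep(1, length(q)),
                              scheme = "decoupling")
  expect_equal(dec1$intensity, ff$intensity, tolerance = 1e-8)
  # decoupling identity: I_dec - <F^2> S = (<F^2> - <F>^2)(1 - S) >= 0 for S <= 1
  dec2 <- effective_intensity(amp, d, q, S_q = Sq, scheme = "decoupling")
  gap <- dec2$intensity - ff$intensity * Sq
  expect_true(all(gap[Sq <= 1] >= -1e-8 * max(ff$intensity)))
})

test_that("spinodal-like instability raises a typed error rather than returning unphysical S", {
  expect_error(
    oz_solve(potential_two_yukawa(1, K1 = 20, Z1 = 2, K2 = 0, Z2 = 1), "MSA",
             eta = 0.3, grid = oz_grid(2^11, 1 / 100)),
    "spinodal|converge|overflow")
})
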