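test_that("metalog quantile reproduces closed-form special cases", {
  p <- metalog_params(c(3, 1))
  expect_equal(metalog_quantile(0.5, p), 3)           # all terms but a1 vanish
  expect_equal(metalog_quantile(0.75, p), 3 + log(3), tolerance = 1e-12)
  # y = 0.5 kills every term beyond a1 for any k
  p10 <- metalog_params(c(7, 0.5, 0.1, -0.2, 0.05, 0.01, 0.02, -0.01, 0.003, 0.001),
                        check_feasible = FALSE)
  expect_equal(metalog_quantile(0.5, p10), 7)
  expect_error(metalog_quantile(0, p), "inside")
  expect_error(metalog_quantile(1.2, p), "inside")
})

test_that("lower-bounded 2-term metalog is a log-logistic law", {
  mu <- 1.7; s <- 0.3
  p <- metalog_params(c(mu, s), boundedness = "lower", b_l = 0)
  y <- c(0.1, 0.25, 0.5, 0.9)
  # independent log-logistic quantile formula
  expect_equal(metalog_quantile(y, p), exp(mu) * (y / (1 - y))^s, tolerance = 1e-12)
  expect_equal(metalog_quantile(0.5, p), exp(mu))
})

test_that("metalog pdf is the reciprocal quantile density and integrates to one", {
  p <- metalog_params(c(0, 1))
  expect_equal(metalog_pdf(0.5, p), 0.25)  # dM/dy = 1/(y(1-y)) = 4 at y = 1/2
  # change of variables: int p(x) dx = int dy = 1 for any feasible metalog
  for (pp in list(p,
                  metalog_params(c(10, 0.5, 0.2, 1)),
                  metalog_params(c(2, 0.4), boundedness = "lower", b_l = 1),
                  metalog_params(c(0, 0.8), boundedness = "both", b_l = 2, b_u = 9))) {
    # logit-dense parametric grid resolves the tails/edge spikes
    t <- seq(log(1e-9), -log(1e-9), length.out = 200001)
    y <- stats::plogis(t)
    x <- metalog_quantile(y, pp)
    expect_equal(pracma::trapz(x, metalog_pdf(y, pp)), 1, tolerance = 1e-5)
  }
})

test_that("feasibility is decided on a dense quantile-density grid", {
  expect_true(metalog_feasible(metalog_params(c(0, 1))))
  expect_false(metalog_feasible(metalog_params(c(0, -1), check_feasible = FALSE)))
  # dM/dy = 1/(y(1-y)) - 10 dips negative near y = 0.5
  expect_false(metalog_feasible(metalog_params(c(0, 1, 0, -10), check_feasible = FALSE)))
  expect_error(metalog_params(c(0, -1)), "infeasible")
})

test_that("quantile fitting recovers exact coefficients and rejects degenerate designs", {
  y <- seq(0.1, 0.9, by = 0.1)
  x <- metalog_quantile(y, metalog_params(c(3, 1)))
  fit <- fit_metalog_to_quantiles(x, y, k = 2)
  expect_equal(fit$a, c(3, 1), tolerance = 1e-10)
  expect_error(fit_metalog_to_quantiles(c(x, x[1]), c(y, y[1]), k = 2), "duplicate")
  expect_error(fit_metalog_to_quantiles(x[1:3], y[1:3], k = 5), "at least k")
})

test_that("a 10-term metalog reproduces the standard normal CDF closely", {
  y <- seq(0.02, 0.98, length.out = 19)
  fit <- fit_metalog_to_quantiles(stats::qnorm(y), y, k = 10)
  expect_true(isTRUE(attr(fit, "feasible")))
  yg <- seq(1e-4, 1 - 1e-4, length.out = 2000)
  # compare CDFs parametrically: F_metalog(Q(y)) = y vs Phi(Q(y))
  xg <- metalog_quantile(yg, fit)
  expect_lt(max(abs(stats::pnorm(xg) - yg)), 1e-3)
})

test_that("fitted quantiles reproduce the inputs within the fit residual", {
  set.seed(4)
  y <- sort(stats::runif(25, 0.02, 0.98))
  x <- stats::qlnorm(y, log(5), 0.3)
  fit <- fit_metalog_to_quantiles(x, y, k = 6, boundedness = "lower", b_l = 0)
  resid <- attr(fit, "residual")
  # residual is in log space for the lower-bounded transform
  expect_lt(max(abs(log(metalog_quantile(y, fit)) - log(x))),
            max(10 * resid, 1e-8))
})

test_that("distribution integral reduces to the monodisperse curve for delta and near-delta inputs", {
  q <- exp(seq(log(0.02), log(0.4), length.out = 30))  # qR <= 4: off the zeros
  d0 <- dist_delta(10)
  I <- integrate_over_distribution(function(q, x) sphere_intensity(q, x), d0, q)
  expect_equal(I$intensity, sphere_intensity(q, 10), tolerance = 1e-12)
  dn <- dist_metalog(metalog_params(c(10, 0.01)))
  In <- integrate_over_distribution(function(q, x) sphere_intensity(q, x), dn, q)
  expect_lt(max(abs(In$intensity - sphere_intensity(q, 10)) / sphere_intensity(q, 10)),
            0.005)
})

test_that("lognormal integration matches a brute-force 10000-node trapezoid oracle", {
  d <- dist_lognormal(10, 0.1)
  q <- exp(seq(log(0.02), log(2), length.out = 50))
  I <- integrate_over_distribution(function(q, x) sphere_intensity(q, x), d, q)
  xg <- seq(stats::qlnorm(1e-9, log(10), 0.1), stats::qlnorm(1 - 1e-9, log(10), 0.1),
            length.out = 10001)
  oracle <- vapply(q, function(qq) {
    amp <- 3 * (sin(qq * xg) - qq * xg * cos(qq * xg)) / (qq * xg)^3
    pracma::trapz(xg, (4 * pi / 3 * xg^3 * amp)^2 * stats::dlnorm(xg, log(10), 0.1))
  }, numeric(1))
  expect_lt(max(abs(I$intensity - oracle) / oracle), 1e-6)
})

test_that("quantile-space integration reproduces closed-form metalog moments", {
  # unbounded (a1, a2): logistic in x, E[x] = a1, E[x^2] = a1^2 + a2^2 pi^2/3
  for (a in list(c(10, 0.3), c(10, 0.001))) {
    d <- dist_metalog(metalog_params(a))
    m1 <- integrate_over_distribution(function(q, x) x + 0 * q, d, q = 1)$intensity
    m2 <- integrate_over_distribution(function(q, x) x^2 + 0 * q, d, q = 1)$intensity
    expect_equal(m1, a[1], tolerance = 1e-7)
    expect_equal(m2, a[1]^2 + a[2]^2 * pi^2 / 3, tolerance = 1e-7)
  }
  # lower-bounded (mu, s): log-logistic, E[x^n] = e^(n mu) n pi s / sin(n pi s)
  mu <- 2; s <- 0.1
  d <- dist_metalog(metalog_params(c(mu, s), boundedness = "lower", b_l = 0))
  m1 <- integrate_over_distribution(function(q, x) x + 0 * q, d, q = 1)$intensity
  m2 <- integrate_over_distribution(function(q, x) x^2 + 0 * q, d, q = 1)$intensity
  expect_equal(m1, exp(mu) * pi * s / sin(pi * s), tolerance = 1e-6)
  expect_equal(m2, exp(2 * mu) * 2 * pi * s / sin(2 * pi * s), tolerance = 1e-6)
})

test_that("integration stays finite from very sharp to very broad shapes without tuning", {
  q <- exp(seq(log(0.05), log(1), length.out = 20))
  for (pp in list(metalog_params(c(10, 0.001)),
                  metalog_params(c(log(10), 0.8), boundedness = "lower", b_l = 0),
                  metalog_params(c(3, 0.6, 0.2, 0.5), boundedness = "lower", b_l = 1))) {
    I <- integrate_over_distribution(function(q, x) sphere_intensity(q, x),
                                     dist_metalog(pp), q)
    expect_true(all(is.finite(I$intensity)))
    expect_true(all(I$intensity > 0))
  }
})

test_that("volume weighting divides the kernel by the particle volume", {
  d <- dist_delta(5)
  q <- c(0.05, 0.1)
  In <- integrate_over_distribution(function(q, x) sphere_intensity(q, x), d, q)
  Iv <- integrate_over_distribution(function(q, x) sphere_intensity(q, x), d, q,
                                    weighting = "volume")
  expect_equal(Iv$intensity, In$intensity / (4 * pi / 3 * 5^3), tolerance = 1e-12)
})
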