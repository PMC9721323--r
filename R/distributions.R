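#' Metalog parameter set
#'
#' The metalog is a quantile-parameterized distribution: its quantile
#' function (inverse CDF) is a linear combination of logit-polynomial basis
#' terms in the cumulative probability `y`,
#' \deqn{M_k(y) = \sum_{j=1}^{k} a_j\, g_j(y),}
#' with basis sequence
#' \eqn{1,\; L,\; (y-\tfrac12)L,\; (y-\tfrac12),\; (y-\tfrac12)^2,\;
#' (y-\tfrac12)^2 L,\; (y-\tfrac12)^3,\; (y-\tfrac12)^3 L,\;
#' (y-\tfrac12)^4,\; (y-\tfrac12)^4 L}
#' where \eqn{L = \ln[y/(1-y)]}. Between 2 and 10 terms are supported.
#' The unbounded variant returns \eqn{M_k(y)} directly; the left-bounded
#' variant returns \eqn{b_l + e^{M_k(y)}}; the doubly bounded variant returns
#' \eqn{(b_l + b_u e^{M_k(y)})/(1 + e^{M_k(y)})}.
#'
#' @param a Numeric coefficient vector, length 2..10.
#' @param boundedness One of `"unbounded"`, `"lower"`, `"both"`.
#' @param b_l Lower bound (required for `"lower"` and `"both"`).
#' @param b_u Upper bound (required for `"both"`; must exceed `b_l`).
#' @param check_feasible If `TRUE` (default) an infeasible coefficient vector
#'   (non-monotone quantile function) raises an error.
#' @return An object of class `metalog_params`.
#' @export
metalog_params <- function(a, boundedness = c("unbounded", "lower", "both"),
                           b_l = NULL, b_u = NULL, check_feasible = TRUE) {
  boundedness <- match.arg(boundedness)
  a <- as.numeric(a)
  k <- length(a)
  if (k < 2L || k > 10L) stop("metalog needs between 2 and 10 coefficients")
  if (any(!is.finite(a))) stop("coefficients must be finite")
  if (boundedness %in% c("lower", "both")) {
    if (is.null(b_l) || !is.finite(b_l)) stop("b_l required for bounded metalog")
  }
  if (boundedness == "both") {
    if (is.null(b_u) || !is.finite(b_u)) stop("b_u required for doubly bounded metalog")
    if (b_l >= b_u) stop("b_l must be smaller than b_u")
  }
  p <- structure(list(a = a, k = k, boundedness = boundedness,
                      b_l = b_l, b_u = b_u),
                 class = "metalog_params")
  if (check_feasible && !metalog_feasible(p))
    stop("infeasible metalog coefficients: quantile density not positive")
  p
}

# basis matrix g_j(y), j = 1..k, on the canonical metalog term ordering
.metalog_basis <- function(y, k) {
  L <- log(y / (1 - y))
  d <- y - 0.5
  cols <- list(rep(1, length(y)), L, d * L, d, d^2, d^2 * L, d^3, d^3 * L,
               d^4, d^4 * L)
  do.call(cbind, cols[seq_len(k)])
}

# termwise derivative dg_j/dy; dL/dy = 1/(y(1-y))
.metalog_basis_dy <- function(y, k) {
  L <- log(y / (1 - y))
  d <- y - 0.5
  dL <- 1 / (y * (1 - y))
  cols <- list(rep(0, length(y)), dL, L + d * dL, rep(1, length(y)),
               2 * d, 2 * d * L + d^2 * dL, 3 * d^2, 3 * d^2 * L + d^3 * dL,
               4 * d^3, 4 * d^3 * L + d^4 * dL)
  do.call(cbind, cols[seq_len(k)])
}

.check_y <- function(y) {
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    stop("y must lie strictly inside (0, 1)")
  y
}

# M_k(y) before any boundedness transform
.metalog_M <- function(y, params) {
  drop(.metalog_basis(y, params$k) %*% params$a)
}

# dM_k/dy
.metalog_dM <- function(y, params) {
  drop(.metalog_basis_dy(y, params$k) %*% params$a)
}

#' Metalog quantile function
#'
#' Evaluates the quantile (inverse CDF) \eqn{x = Q(y)} of a metalog
#' distribution. At `y = 0.5` the unbounded metalog returns `a[1]` exactly.
#'
#' @param y Cumulative probabilities, strictly inside (0, 1); vectorized.
#' @param params A [metalog_params()] object.
#' @return Numeric vector of sizes `x`.
#' @export
metalog_quantile <- function(y, params) {
  stopifnot(inherits(params, "metalog_params"))
  .check_y(y)
  M <- .metalog_M(y, params)
  switch(params$boundedness,
    unbounded = M,
    lower = params$b_l + exp(M),
    both = (params$b_l + params$b_u * exp(M)) / (1 + exp(M))
  )
}

#' Metalog probability density
#'
#' Density of the metalog at the point `x = metalog_quantile(y, params)`,
#' obtained as the reciprocal quantile density \eqn{p(x) = 1/q(y)} with
#' \eqn{q(y) = dQ/dy} evaluated analytically (termwise derivative plus the
#' chain-rule factor of the boundedness transform).
#'
#' @inheritParams metalog_quantile
#' @return Numeric vector of densities.
#' @export
metalog_pdf <- function(y, params) {
  stopifnot(inherits(params, "metalog_params"))
  .check_y(y)
  dM <- .metalog_dM(y, params)
  if (any(dM <= 0)) stop("non-positive quantile density: infeasible parameters")
  switch(params$boundedness,
    unbounded = 1 / dM,
    lower = {
      M <- .metalog_M(y, params)
      1 / (dM * exp(M))
    },
    both = {
      M <- .metalog_M(y, params)
      eM <- exp(M)
      (1 + eM)^2 / (dM * eM * (params$b_u - params$b_l))
    }
  )
}

#' Metalog feasibility check
#'
#' A metalog coefficient vector is feasible when the quantile density
#' \eqn{dM_k/dy} is strictly positive everywhere in (0, 1). The check is
#' performed on a fixed dense grid (default 10001 equispaced interior
#' points), which is cheap, deterministic and adequate for k <= 10.
#'
#' @param params A `metalog_params` object (feasibility is not re-checked on
#'   construction input here) or a bare list with elements `a`, `k`.
#' @param n_grid Number of interior grid points.
#' @return `TRUE` if feasible on the grid.
#' @export
metalog_feasible <- function(params, n_grid = 10001L) {
  y <- seq_len(n_grid) / (n_grid + 1)
  all(.metalog_dM(y, params) > 0)
}

#' Metalog cumulative distribution function
#'
#' Numerical inversion of the quantile function by bisection; the metalog is
#' defined through \eqn{Q(y)}, so \eqn{F(x)} has no closed form.
#'
#' @param x Sizes at which to evaluate the CDF; vectorized.
#' @param params A [metalog_params()] object.
#' @return Cumulative probabilities in (0, 1).
#' @export
metalog_cdf <- function(x, params) {
  stopifnot(inherits(params, "metalog_params"))
  lo <- 1e-12; hi <- 1 - 1e-12
  xlo <- metalog_quantile(lo, params)
  xhi <- metalog_quantile(hi, params)
  vapply(x, function(xx) {
    if (xx <= xlo) return(lo)
    if (xx >= xhi) return(hi)
    stats::uniroot(function(y) metalog_quantile(y, params) - xx,
                   lower = lo, upper = hi, tol = 1e-13)$root
  }, numeric(1))
}

#' Fit a metalog to quantile data
#'
#' Least-squares fit of the metalog coefficients to CDF data pairs
#' `(x, y)`: the (possibly bound-transformed) sizes are regressed linearly on
#' the metalog basis evaluated at the `y` values. This fits the cumulative
#' distribution directly rather than the density.
#'
#' @param x Sizes (quantile values).
#' @param y Corresponding cumulative probabilities in (0, 1), all distinct.
#' @param k Number of metalog terms (2..10); at least `k` pairs required.
#' @param boundedness,b_l,b_u See [metalog_params()].
#' @return A [metalog_params()] object with attribute `residual` (RMS of the
#'   linear fit). If the fitted coefficients are infeasible a warning is
#'   issued and the attribute `feasible` is `FALSE`.
#' @export
fit_metalog_to_quantiles <- function(x, y, k,
                                     boundedness = c("unbounded", "lower", "both"),
                                     b_l = NULL, b_u = NULL) {
  boundedness <- match.arg(boundedness)
  .check_y(y)
  if (anyDuplicated(y)) stop("duplicate y values: degenerate design")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(y) < k) stop("need at least k quantile pairs")
  z <- switch(boundedness,
    unbounded = x,
    lower = {
      if (any(x <= b_l)) stop("x must exceed b_l for a left-bounded metalog")
      log(x - b_l)
    },
    both = {
      if (any(x <= b_l) || any(x >= b_u)) stop("x must lie inside (b_l, b_u)")
      log((x - b_l) / (b_u - x))
    }
  )
  B <- .metalog_basis(y, k)
  qrB <- qr(B)
  if (qrB$rank < k) stop("rank-deficient basis matrix")
  a <- qr.coef(qrB, z)
  p <- metalog_params(a, boundedness, b_l, b_u, check_feasible = FALSE)
  feas <- metalog_feasible(p)
  if (!feas) warning("fitted metalog coefficients are infeasible")
  attr(p, "feasible") <- feas
  attr(p, "residual") <- sqrt(mean((drop(B %*% a) - z)^2))
  p
}

#' Size-distribution constructors
#'
#' A `size_distribution` bundles a distribution family with its parameters
#' and exposes `dist_pdf()`, `dist_quantile()` and `dist_support()`.
#' Lognormals are parameterized by the median `m` and the shape `s`
#' (standard deviation of `ln x`). The bimodal lognormal mixes two lognormal
#' components with number-weight `w` on the first.
#'
#' @param median,shape Median (nm) and log-space standard deviation.
#' @return An object of class `size_distribution`.
#' @export
dist_lognormal <- function(median, shape) {
  stopifnot(median > 0, shape > 0)
  structure(list(kind = "lognormal", median = median, shape = shape),
            class = "size_distribution")
}

#' @rdname dist_lognormal
#' @param median1,shape1,median2,shape2 Component parameters.
#' @param w Number-weight of the first component, in \[0, 1\].
#' @export
dist_bilognormal <- function(median1, shape1, median2, shape2, w = 0.5) {
  stopifnot(median1 > 0, shape1 > 0, median2 > 0, shape2 > 0,
            w >= 0, w <= 1)
  structure(list(kind = "bilognormal", median1 = median1, shape1 = shape1,
                 median2 = median2, shape2 = shape2, w = w),
            class = "size_distribution")
}

#' @rdname dist_lognormal
#' @param location Position of the point mass (nm).
#' @export
dist_delta <- function(location) {
  stopifnot(location > 0)
  structure(list(kind = "delta", location = location),
            class = "size_distribution")
}

#' @rdname dist_lognormal
#' @param params A [metalog_params()] object.
#' @export
dist_metalog <- function(params) {
  stopifnot(inherits(params, "metalog_params"))
  structure(list(kind = "metalog", params = params),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> kind = %s\n", x$kind))
  invisible(x)
}

#' Probability density of a size distribution
#' @param dist A `size_distribution`.
#' @param x Sizes (nm).
#' @return Densities.
#' @export
dist_pdf <- function(dist, x) {
  switch(dist$kind,
    lognormal = stats::dlnorm(x, log(dist$median), dist$shape),
    bilognormal = dist$w * stats::dlnorm(x, log(dist$median1), dist$shape1) +
      (1 - dist$w) * stats::dlnorm(x, log(dist$median2), dist$shape2),
    delta = stop("delta distribution has no density"),
    metalog = {
      y <- metalog_cdf(x, dist$params)
      metalog_pdf(y, dist$params)
    }
  )
}

#' Quantile function of a size distribution
#' @param dist A `size_distribution`.
#' @param y Cumulative probabilities in (0, 1).
#' @return Sizes.
#' @export
dist_quantile <- function(dist, y) {
  switch(dist$kind,
    lognormal = stats::qlnorm(y, log(dist$median), dist$shape),
    bilognormal = {
      # numeric inversion of the mixture CDF
      cdf <- function(x) dist$w * stats::plnorm(x, log(dist$median1), dist$shape1) +
        (1 - dist$w) * stats::plnorm(x, log(dist$median2), dist$shape2)
      rng <- range(stats::qlnorm(c(1e-12, 1 - 1e-12), log(dist$median1), dist$shape1),
                   stats::qlnorm(c(1e-12, 1 - 1e-12), log(dist$median2), dist$shape2))
      vapply(y, function(yy)
        stats::uniroot(function(x) cdf(x) - yy, lower = rng[1], upper = rng[2],
                       tol = 1e-12)$root, numeric(1))
    },
    delta = rep(dist$location, length(y)),
    metalog = metalog_quantile(y, dist$params)
  )
}

#' Effective support of a size distribution
#' @param dist A `size_distribution`.
#' @param eps Tail probability cut (default 1e-7 per side).
#' @return Length-2 numeric vector.
#' @export
dist_support <- function(dist, eps = 1e-7) {
  if (dist$kind == "delta") return(rep(dist$location, 2))
  dist_quantile(dist, c(eps, 1 - eps))
}

# cached Gauss-Legendre nodes
.gl_cache <- new.env(parent = emptyenv())
.gl_nodes <- function(n, a = 0, b = 1) {
  key <- sprintf("%d", n)
  gl <- .gl_cache[[key]]
  if (is.null(gl)) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gl_cache[[key]] <- gl
  }
  list(x = a + (b - a) * gl$x, w = (b - a) * gl$w)
}

#' Integrate a form factor over a size distribution
#'
#' Computes \eqn{I(q) = \int P(q, x)\, p(x)\, dx} for a size distribution.
#' For the metalog the integral is evaluated in quantile space,
#' \eqn{I(q) = \int_0^1 P(q, M_k(y))\, dy} (change of variables; no density
#' factor appears), using fixed-order Gauss-Legendre quadrature on
#' \eqn{[\epsilon, 1-\epsilon]} with \eqn{\epsilon = 10^{-8}}. This is
#' numerically robust for both very sharp and very broad distributions. For
#' lognormal-type distributions composite Gauss-Legendre quadrature over the
#' effective support is used; the delta distribution reduces to the
#' monodisperse evaluation.
#'
#' With `weighting = "number"` the distribution is a number density and the
#' result is the intensity per unit number concentration; with
#' `weighting = "volume"` the distribution is interpreted as volume-weighted
#' (\eqn{D_V = n(x) V(x)}) and each kernel evaluation carries a factor
#' \eqn{1/V(x)} with \eqn{V = (4\pi/3)x^3}.
#'
#' @param form_factor Function `P(q, x)` vectorized in `q` (per-particle
#'   intensity at size `x`).
#' @param dist A `size_distribution`.
#' @param q Numeric vector of scattering vectors (nm^-1).
#' @param weighting `"number"` or `"volume"`.
#' @param n_nodes Quadrature order in quantile space (metalog) and per panel
#'   (x-space).
#' @return A [sas_curve()] with the integrated intensity.
#' @export
integrate_over_distribution <- function(form_factor, dist, q,
                                        weighting = c("number", "volume"),
                                        n_nodes = 601L) {
  weighting <- match.arg(weighting)
  fac <- function(x) if (weighting == "number") rep(1, length(x)) else
    1 / (4 * pi / 3 * x^3)
  if (dist$kind == "delta") {
    x0 <- dist$location
    I <- form_factor(q, x0) * fac(x0)
  } else if (dist$kind == "metalog") {
    # quantile-space integral int_0^1 P(q, Q(y)) dy on [eps, 1-eps],
    # evaluated in the logit variable t = ln(y/(1-y)) so that the power-law
    # boundary layers of heavy-tailed metalogs become smooth exponentials:
    # dy = y(1-y) dt on uniform composite Gauss-Legendre panels in t
    eps <- 1e-8
    L <- log((1 - eps) / eps)
    n_panel <- 36L
    edges_t <- seq(-L, L, length.out = n_panel + 1L)
    I <- numeric(length(q))
    for (p in seq_len(n_panel)) {
      gl <- .gl_nodes(max(8L, n_nodes %/% n_panel), edges_t[p], edges_t[p + 1L])
      ys <- stats::plogis(gl$x)
      xs <- metalog_quantile(ys, dist$params)
      jac <- ys * (1 - ys)
      fx <- fac(xs)
      for (j in seq_along(xs))
        I <- I + gl$w[j] * jac[j] * fx[j] * form_factor(q, xs[j])
    }
  } else {
    # wide support: high moments of the kernel push weight far into the tail
    sup <- dist_support(dist, eps = 1e-11)
    # composite panels, log-spaced to resolve broad distributions
    edges <- exp(seq(log(sup[1]), log(sup[2]), length.out = 9L))
    I <- numeric(length(q))
    for (p in seq_len(length(edges) - 1L)) {
      gl <- .gl_nodes(n_nodes %/% 4L, edges[p], edges[p + 1L])
      pd <- dist_pdf(dist, gl$x) * fac(gl$x)
      for (j in seq_along(gl$x))
        I <- I + gl$w[j] * pd[j] * form_factor(q, gl$x[j])
    }
  }
  if (any(!is.finite(I))) stop("distribution integral did not converge")
  sas_curve(q, I)
}
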