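# Order-0 Hankel transform machinery.
#
# Convention used throughout: the symmetric, self-reciprocal pair
#   g(r) = int_0^inf f(q) J0(qr) q dq
#   f(q) = int_0^inf g(r) J0(qr) r dr
# with no 2*pi in either direction. All physical prefactors (2*pi, lambda^2,
# thickness) live in the multiple-scattering functions.

# int_a^b f(t) J0(t x) t dt: adaptive quadrature per segment (the segment is
# at most half a Bessel period, but f itself may vary on a finer scale)
.hseg <- function(f, a, b, x) {
  g <- function(t) f(t) * besselJ(t * x, 0) * t
  out <- tryCatch(
    stats::integrate(g, a, b, rel.tol = 1e-11, abs.tol = 0,
                     subdivisions = 200L)$value,
    error = function(e) NULL)
  if (is.null(out)) {
    gl <- .gl_nodes(61L, a, b)
    out <- sum(gl$w * g(gl$x))
  }
  out
}

# scalar Hankel integral int_0^upper f(t) J0(tx) t dt.
# Oscillation handled by half-period segments; slowly decaying alternating
# tails accelerated by iterated averaging of the partial sums.
.hankel_point <- function(f, x, upper = Inf, reltol = 1e-10,
                          max_seg = 400L, seg0 = 1) {
  if (x <= 0) {
    # no Bessel oscillation: geometrically growing adaptive panels (fixed-order
    # fallback when f itself oscillates faster than the panel)
    panel <- function(a, b) {
      out <- tryCatch(
        stats::integrate(function(t) f(t) * t, a, b, rel.tol = 1e-10,
                         abs.tol = 0, subdivisions = 400L)$value,
        error = function(e) NULL)
      if (is.null(out)) {
        gl <- .gl_nodes(201L, a, b)
        out <- sum(gl$w * f(gl$x) * gl$x)
      }
      out
    }
    tot <- 0; a <- 0; h <- seg0
    for (k in seq_len(200L)) {
      b <- min(a + h, upper)
      inc <- panel(a, b)
      tot <- tot + inc
      a <- b
      if (a >= upper) break
      h <- h * 1.6
      if (k > 8L && abs(inc) < reltol * max(abs(tot), 1e-300)) break
    }
    return(tot)
  }
  h <- pi / x
  partial <- numeric(0)
  tot <- 0
  a <- 0
  quiet <- 0L
  for (k in seq_len(max_seg)) {
    b <- min(a + h, upper)
    seg <- .hseg(f, a, b, x)
    tot <- tot + seg
    partial <- c(partial, tot)
    a <- b
    if (a >= upper) return(tot)
    if (abs(seg) < reltol * max(abs(tot), 1e-300)) {
      quiet <- quiet + 1L
      if (quiet >= 3L) return(tot)
    } else quiet <- 0L
  }
  # iterated averaging (Euler-type acceleration) of the alternating tail
  m <- min(40L, length(partial))
  u <- utils::tail(partial, m)
  while (length(u) > 1L) u <- (u[-1] + u[-length(u)]) / 2
  u
}

# vectorized driver
.hankel_fn <- function(f, x, upper = Inf, ...) {
  vapply(x, function(xx) .hankel_point(f, xx, upper = upper, ...), numeric(1))
}

# evaluator for a sampled curve: linear interpolation inside the grid,
# power-law continuation beyond q_max (slope fitted on the top quarter of the
# grid), constant below q_min. Returns list(fn, slope).
.curve_evaluator <- function(curve) {
  q <- curve$q; I <- curve$intensity
  n <- length(q)
  itail <- q >= q[max(1L, floor(0.75 * n))]
  pos <- itail & I > 0
  slope <- if (sum(pos) >= 3L) {
    stats::coef(stats::lm(log(I[pos]) ~ log(q[pos])))[[2]]
  } else -Inf  # tail effectively zero
  ap <- stats::approxfun(q, I, rule = 2)
  qmax <- q[n]; Imax <- I[n]
  fn <- function(t) {
    out <- ap(t)
    hi <- t > qmax
    if (any(hi)) out[hi] <- if (is.finite(slope) && Imax > 0)
      Imax * (t[hi] / qmax)^slope else 0
    out
  }
  list(fn = fn, slope = slope)
}

#' Forward Hankel transform of a scattering curve
#'
#' Computes \eqn{g(r) = \int_0^\infty f(q) J_0(qr)\, q\, dq} for a sampled
#' curve or a function. The integrand must decay faster than \eqn{q^{-2}};
#' for sampled curves the tail slope is estimated from the top quarter of the
#' grid and the transform refuses to proceed when it indicates divergence.
#' Beyond the sampled range a fitted power law continues the integrand.
#'
#' @param curve A [sas_curve()] or a function `f(q)`.
#' @param r Output grid (nm), non-negative, strictly increasing.
#' @param q_upper Upper integration limit when `curve` is a function with
#'   compact support (default infinite).
#' @return A [real_space_fn()] on `r`.
#' @export
hankel_forward <- function(curve, r, q_upper = Inf) {
  if (is.function(curve)) {
    f <- curve
  } else {
    stopifnot(.is_curve(curve))
    ev <- .curve_evaluator(curve)
    if (ev$slope >= -2 && is.finite(ev$slope))
      stop("curve tail decays like q^", sprintf("%.2f", ev$slope),
           " (slower than q^-2): Hankel transform diverges")
    f <- ev$fn
    if (!is.finite(q_upper)) q_upper <- Inf
  }
  real_space_fn(r, .hankel_fn(f, r, upper = q_upper))
}

#' Inverse Hankel transform of a real-space function
#'
#' Computes \eqn{f(q) = \int_0^\infty g(r) J_0(qr)\, r\, dr}, the reciprocal
#' member of the self-reciprocal pair used by [hankel_forward()]. Sampled
#' inputs must decay to zero at the end of the grid; beyond it the function
#' is continued by zero.
#'
#' @param realspace A [real_space_fn()] or a function `g(r)`.
#' @param q Output grid (nm^-1).
#' @param r_upper Upper integration limit when `realspace` is a function.
#' @return A [sas_curve()] on `q`.
#' @export
hankel_inverse <- function(realspace, q, r_upper = Inf) {
  if (is.function(realspace)) {
    g <- realspace
    upper <- r_upper
  } else {
    stopifnot(inherits(realspace, "real_space_fn"))
    v <- realspace$value
    vmax <- max(abs(v))
    if (vmax > 0 && mean(abs(utils::tail(v, max(3L, length(v) %/% 20L)))) > 1e-3 * vmax)
      stop("real-space input does not decay to zero at the end of its grid")
    # computed real-space functions are smooth: natural cubic spline
    sp <- stats::splinefun(realspace$r, v, method = "natural")
    rmax <- max(realspace$r); rmin <- min(realspace$r)
    g <- function(t) ifelse(t > rmax, 0, sp(pmax(t, rmin)))
    upper <- rmax
  }
  sas_curve(q, .hankel_fn(g, q, upper = upper))
}
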