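#' Default size grid for inversion
#'
#' Log-spaced size-bin centers spanning `pi/q_max` to `pi/q_min`, the range
#' of sizes to which the measured q window is sensitive.
#'
#' @param q Scattering-vector grid (nm^-1).
#' @param n Number of bins (default 100).
#' @return Numeric vector of bin centers (nm), strictly increasing.
#' @export
default_size_grid <- function(q, n = 100L) {
  exp(seq(log(pi / max(q)), log(pi / min(q)), length.out = n))
}

#' Build the discretized Fredholm kernel
#'
#' Discretizes the forward map of the size-distribution problem,
#' \eqn{I(q_i) = \int K(q_i, R)\, x(R)\, dR}, as a matrix
#' \eqn{A_{ij} = P(q_i, R_j)\, w(R_j)\, \Delta R_j}. With
#' `weighting = "number"` the solution vector is the number density
#' (\eqn{w = 1}); with `weighting = "volume"` it is the volume-weighted
#' distribution \eqn{D_V = n V} (\eqn{w = 1/V(R)}).
#'
#' @param q Scattering-vector grid (nm^-1), strictly increasing.
#' @param R Size-bin centers (nm), strictly increasing.
#' @param model Function `P(q, R)` (per-particle intensity), vectorized in
#'   `q`, non-negative.
#' @param weighting `"number"` or `"volume"`.
#' @return An object of class `kernel_matrix` with fields `A`, `q`, `R`,
#'   `dR`, `weighting`.
#' @export
build_kernel <- function(q, R, model = function(q, R) sphere_intensity(q, R),
                         weighting = c("number", "volume")) {
  weighting <- match.arg(weighting)
  if (length(q) == 0L || length(R) == 0L) stop("empty grids")
  if (any(diff(q) <= 0) || (length(R) > 1L && any(diff(R) <= 0)))
    stop("grids must be strictly increasing")
  # bin widths from midpoints, end bins extended symmetrically
  dR <- if (length(R) == 1L) 1 else {
    mid <- (R[-1] + R[-length(R)]) / 2
    diff(c(2 * R[1] - mid[1], mid, 2 * R[length(R)] - mid[length(mid)]))
  }
  w <- if (weighting == "number") rep(1, length(R)) else 1 / (4 * pi / 3 * R^3)
  A <- matrix(0, nrow = length(q), ncol = length(R))
  for (j in seq_along(R)) A[, j] <- model(q, R[j]) * w[j] * dR[j]
  if (any(A < 0)) stop("kernel must be non-negative")
  structure(list(A = A, q = q, R = R, dR = dR, weighting = weighting),
            class = "kernel_matrix")
}

.kernel_A <- function(kernel) {
  if (inherits(kernel, "kernel_matrix")) kernel$A else as.matrix(kernel)
}

#' Regularization operator
#'
#' @param n Solution length.
#' @param kind `"identity"`, `"d1"` (first differences) or `"d2"` (second
#'   differences).
#' @return Matrix with `n` columns.
#' @export
reg_operator <- function(n, kind = c("identity", "d1", "d2")) {
  kind <- match.arg(kind)
  ord <- switch(kind, identity = 0L, d1 = 1L, d2 = 2L)
  if (ord == 0L) return(diag(n))
  if (n <= ord) return(matrix(0, 0L, n))
  diff(diag(n), differences = ord)
}

.new_inversion_result <- function(x, lambda, chi2, cost, iterations, scheme,
                                  flags = character(), lcurve = NULL,
                                  likelihood = NULL) {
  structure(list(x = x, lambda = lambda, chi2 = chi2, cost = cost,
                 iterations = iterations, scheme = scheme, flags = flags,
                 lcurve = lcurve, likelihood = likelihood),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> scheme = %s, lambda = %g, chi2 = %g, iterations = %s\n",
              x$scheme, x$lambda, x$chi2,
              if (is.na(x$iterations)) "-" else x$iterations))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tikhonov-regularized inversion
#'
#' Solves \eqn{\min_x \|\Sigma^{-1}(Ax - y)\|^2 + \lambda \|Lx\|^2} for a
#' scattering curve `y` with uncertainties, where `L` is the identity or a
#' first/second-order difference operator. No positivity constraint is
#' imposed. At `lambda = 0` a singular system falls back to the minimum-norm
#' (pseudoinverse) solution and the result is flagged `"minimum_norm"`.
#'
#' @param kernel A [build_kernel()] result (or plain matrix).
#' @param curve A [sas_curve()] with `sigma` present.
#' @param L Cost operator: `"identity"`, `"d1"` or `"d2"`.
#' @param lambda Regularization weight, >= 0.
#' @return An `inversion_result` with fields `x`, `lambda`, `chi2` (weighted
#'   residual sum of squares), `cost` (`||Lx||^2`).
#' @export
tikhonov_solve <- function(kernel, curve, L = c("identity", "d1", "d2"),
                           lambda = 0) {
  L <- match.arg(L)
  A <- .kernel_A(kernel)
  stopifnot(.is_curve(curve), !is.null(curve$sigma), lambda >= 0)
  y <- curve$intensity
  sig <- curve$sigma
  Aw <- A / sig
  yw <- y / sig
  Lm <- reg_operator(ncol(A), L)
  flags <- character()
  M <- crossprod(Aw) + lambda * crossprod(Lm)
  b <- crossprod(Aw, yw)
  x <- tryCatch(drop(solve(M, b)), error = function(e) NULL)
  if (is.null(x)) {
    # singular normal equations: minimum-norm least squares via SVD
    sv <- svd(rbind(Aw, if (lambda > 0) sqrt(lambda) * Lm))
    rhs <- c(yw, if (lambda > 0) numeric(nrow(Lm)))
    keep <- sv$d > max(sv$d) * 1e-12
    x <- drop(sv$v[, keep, drop = FALSE] %*%
                ((crossprod(sv$u[, keep, drop = FALSE], rhs)) / sv$d[keep]))
    flags <- "minimum_norm"
  }
  resid <- drop(A %*% x) - y
  .new_inversion_result(x, lambda,
                        chi2 = sum((resid / sig)^2),
                        cost = sum(drop(Lm %*% x)^2),
                        iterations = NA_integer_,
                        scheme = paste0("tikhonov_", L), flags = flags)
}

# symmetric binomial smoothing kernel of odd width, reflective boundary
.binomial_smooth <- function(x, width = 5L) {
  stopifnot(width %% 2L == 1L, width >= 1L)
  if (width == 1L) return(x)
  w <- choose(width - 1L, 0:(width - 1L))
  w <- w / sum(w)
  h <- (width - 1L) %/% 2L
  n <- length(x)
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[n - seq_len(h)]))
  drop(stats::filter(xp, w, sides = 2))[(h + 1L):(h + n)]
}

#' Poisson-type log-likelihood of an EM iterate
#'
#' \eqn{\ell(x) = \sum_i [y_i \ln(Ax)_i - (Ax)_i]} (terms with `y_i = 0`
#' contribute only `-(Ax)_i`). The plain Richardson-Lucy iteration increases
#' this quantity monotonically.
#'
#' @param kernel Kernel matrix (or `kernel_matrix` object).
#' @param x Positive solution vector.
#' @param y Non-negative data vector.
#' @return Scalar log-likelihood.
#' @export
em_likelihood <- function(kernel, x, y) {
  A <- .kernel_A(kernel)
  if (any(x <= 0)) stop("x must be strictly positive")
  mu <- drop(A %*% x)
  pos <- y > 0
  if (any(mu[pos] <= 0)) stop("model intensity vanished where data is positive")
  sum(y[pos] * log(mu[pos])) - sum(mu)
}

#' Expectation-maximization size-distribution retrieval
#'
#' Multiplicative fixed-point iteration for non-negative solutions of the
#' discretized Fredholm problem. The plain scheme is the Richardson-Lucy
#' update
#' \deqn{x_j \leftarrow x_j \frac{\sum_i A_{ij}\, y_i/(Ax)_i}{\sum_i A_{ij}};}
#' the smoothed scheme composes each update with a linear smoothing operator
#' applied in log space (symmetric binomial kernel, reflective boundary,
#' blended with weight `weight`); the entropy schemes apply the
#' multiplicative correction \eqn{(\tilde p_j/\tilde x_j)^{w}} toward a fixed
#' (default uniform) or adaptive (smoothed running iterate) prior, where the
#' tildes denote normalization to unit sum.
#'
#' Data and kernel rows are jointly rescaled by `1/sigma_i` so the weighted
#' problem keeps the non-negative measure structure the iteration requires.
#' Negative intensities are floored at a small epsilon and flagged.
#'
#' @param kernel A [build_kernel()] result.
#' @param curve A [sas_curve()]; `sigma` used as weights when present.
#' @param scheme One of `"plain"`, `"smoothed"`, `"entropy_fixed_prior"`,
#'   `"entropy_adaptive_prior"`.
#' @param weight Regularization weight: smoothing blend in (0, 1\] for
#'   `"smoothed"` (default 1), entropy strength for the entropy schemes
#'   (default 1e-3). Ignored for `"plain"`.
#' @param prior Optional positive prior vector (entropy schemes).
#' @param x0 Optional positive starting vector.
#' @param max_iter,tol Stopping rule: relative L2 change of `x` below `tol`
#'   or `max_iter` iterations.
#' @param smooth_width Odd width of the binomial smoothing kernel.
#' @param keep_likelihood If `TRUE`, store the likelihood trace of the
#'   weighted problem in the result.
#' @return An `inversion_result`; `x` is entrywise positive, `cost` is the
#'   scheme's regularization cost (second-difference smoothness for plain and
#'   smoothed, Kullback-Leibler divergence from the prior for the entropy
#'   schemes).
#' @export
em_iterate <- function(kernel, curve,
                       scheme = c("plain", "smoothed", "entropy_fixed_prior",
                                  "entropy_adaptive_prior"),
                       weight = NULL, prior = NULL, x0 = NULL,
                       max_iter = 1e5L, tol = 1e-7, smooth_width = 5L,
                       keep_likelihood = FALSE) {
  scheme <- match.arg(scheme)
  A <- .kernel_A(kernel)
  stopifnot(.is_curve(curve))
  y <- curve$intensity
  flags <- character()
  if (any(y < 0)) {
    y <- pmax(y, 1e-10 * max(abs(y)))
    flags <- c(flags, "negative_data_floored")
  }
  sig <- curve$sigma %||% rep(1, length(y))
  Aw <- A / sig
  yw <- y / sig
  allzero <- rowSums(Aw) == 0
  if (any(allzero & yw > 0)) stop("kernel row vanishes where data is positive")
  s <- colSums(Aw)
  if (any(s <= 0)) stop("kernel column sums must be positive")
  if (is.null(weight))
    weight <- switch(scheme, plain = 0, smoothed = 1,
                     entropy_fixed_prior = 1e-3, entropy_adaptive_prior = 1e-3)
  if (is.null(prior)) prior <- rep(1, ncol(A))
  if (any(prior <= 0)) stop("prior must be strictly positive")
  x <- x0 %||% rep(sum(yw) / sum(s), ncol(A))
  if (any(x <= 0)) stop("x0 must be strictly positive")
  lik <- if (keep_likelihood) numeric(max_iter) else NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- drop(Aw %*% x)
    if (any(mu <= 0 & yw > 0)) stop("(Ax) vanished where data is positive")
    ratio <- ifelse(mu > 0, yw / mu, 0)
    xr <- x * drop(crossprod(Aw, ratio)) / s
    xn <- switch(scheme,
      plain = xr,
      smoothed = {
        lx <- log(pmax(xr, 1e-300))
        exp((1 - weight) * lx + weight * .binomial_smooth(lx, smooth_width))
      },
      entropy_fixed_prior = {
        pt <- prior / sum(prior)
        xt <- xr / sum(xr)
        xr * (pt / xt)^weight
      },
      entropy_adaptive_prior = {
        pa <- .binomial_smooth(xr, smooth_width)
        pa <- pmax(pa, 1e-300)
        pt <- pa / sum(pa)
        xt <- xr / sum(xr)
        xr * (pt / xt)^weight
      }
    )
    if (keep_likelihood) lik[iter] <- em_likelihood(Aw, xn, yw)
    delta <- sqrt(sum((xn - x)^2) / sum(x^2))
    x <- xn
    if (delta < tol || iter >= max_iter) break
  }
  if (iter >= max_iter && delta >= tol) flags <- c(flags, "max_iter_reached")
  resid <- drop(A %*% x) - curve$intensity
  d2 <- reg_operator(ncol(A), "d2")
  cost <- if (scheme %in% c("entropy_fixed_prior", "entropy_adaptive_prior")) {
    pt <- prior / sum(prior); xt <- x / sum(x)
    sum(xt * log(xt / pt))
  } else if (nrow(d2) > 0L) sum(drop(d2 %*% x)^2) else 0
  .new_inversion_result(x, lambda = weight,
                        chi2 = sum((resid / sig)^2), cost = cost,
                        iterations = iter, scheme = paste0("em_", scheme),
                        flags = flags,
                        likelihood = if (keep_likelihood) lik[seq_len(iter)])
}

#' L-curve corner selection
#'
#' Given inversion results over a ladder of regularization weights, locates
#' the corner of the L-curve: the point of maximal Menger curvature of the
#' (log chi2, log cost) polyline, computed by finite differences over the
#' ladder sorted by lambda. Ties resolve to the smaller lambda. When the
#' points are (numerically) collinear there is no corner; the median lambda
#' is returned with a warning flag.
#'
#' @param results List of `inversion_result` objects, or a data.frame with
#'   columns `lambda`, `chi2`, `cost`; at least 5 entries with distinct
#'   lambdas.
#' @return List with elements `lambda`, `index` (into the lambda-sorted
#'   ladder), `curvature` (vector) and `flag` (`"no_corner"` or empty).
#' @export
lcurve_select <- function(results) {
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      data.frame(lambda = r$lambda, chi2 = r$chi2, cost = r$cost)))
  if (nrow(df) < 5L) stop("need at least 5 ladder points")
  if (anyDuplicated(df$lambda)) stop("lambdas must be distinct")
  if (any(!is.finite(df$chi2)) || any(!is.finite(df$cost)))
    stop("chi2 and cost must be finite")
  df <- df[order(df$lambda), ]
  lx <- log(pmax(df$chi2, 1e-300))
  ly <- log(pmax(df$cost, 1e-300))
  n <- nrow(df)
  kappa <- rep(0, n)
  for (i in 2:(n - 1)) {
    p1 <- c(lx[i - 1], ly[i - 1]); p2 <- c(lx[i], ly[i]); p3 <- c(lx[i + 1], ly[i + 1])
    a <- p2 - p1; b <- p3 - p2; cvec <- p3 - p1
    cross <- a[1] * b[2] - a[2] * b[1]
    dens <- sqrt(sum(a^2)) * sqrt(sum(b^2)) * sqrt(sum(cvec^2))
    kappa[i] <- if (dens > 0) 2 * abs(cross) / dens else 0
  }
  scale <- max(kappa)
  if (scale <= 1e-10) {
    warning("L-curve is degenerate (no corner); returning median lambda")
    idx <- (n + 1L) %/% 2L
    return(list(lambda = df$lambda[idx], index = idx, curvature = kappa,
                flag = "no_corner"))
  }
  idx <- which(kappa >= scale - 1e-12 * scale)[1]  # ties -> smaller lambda
  list(lambda = df$lambda[idx], index = idx, curvature = kappa, flag = "")
}

#' Full size-distribution retrieval with automatic weight selection
#'
#' Convenience driver: runs the chosen scheme over a logarithmic ladder of
#' regularization weights, selects the weight by [lcurve_select()], and
#' returns the corresponding solution with the ladder attached.
#'
#' @param kernel,curve See [tikhonov_solve()] / [em_iterate()].
#' @param scheme `"tikhonov"` or one of the EM schemes.
#' @param L Cost operator for the Tikhonov path.
#' @param lambdas Weight ladder; defaults to 15 log-spaced values spanning a
#'   decade range scaled from the data.
#' @param ... Passed on to the scheme function.
#' @return The selected `inversion_result`, with `lcurve` holding the ladder
#'   data frame.
#' @export
fit_size_distribution <- function(kernel, curve,
                                  scheme = c("tikhonov", "plain", "smoothed",
                                             "entropy_fixed_prior",
                                             "entropy_adaptive_prior"),
                                  L = "d2", lambdas = NULL, ...) {
  scheme <- match.arg(scheme)
  if (!is.null(lambdas)) lambdas <- sort(lambdas)
  if (scheme == "tikhonov") {
    if (is.null(lambdas)) {
      A <- .kernel_A(kernel)
      sig <- curve$sigma %||% rep(1, length(curve$intensity))
      s0 <- sum((A / sig)^2) / ncol(A)
      lambdas <- s0 * 10^seq(-8, 2, length.out = 15L)
    }
    runs <- lapply(lambdas, function(l) tikhonov_solve(kernel, curve, L, l))
  } else {
    if (is.null(lambdas))
      lambdas <- if (scheme == "smoothed") seq(0.05, 1, length.out = 15L)
        else 10^seq(-6, 0, length.out = 15L)
    runs <- lapply(lambdas, function(l)
      em_iterate(kernel, curve, scheme, weight = l, ...))
  }
  sel <- lcurve_select(runs)
  out <- runs[[sel$index]]
  out$lcurve <- do.call(rbind, lapply(runs, function(r)
    data.frame(lambda = r$lambda, chi2 = r$chi2, cost = r$cost)))
  out
}
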