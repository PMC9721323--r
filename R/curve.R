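#' One-dimensional scattering curve
#'
#' Container for a measured or simulated small-angle scattering curve: the
#' scattering-vector modulus `q` (nm^-1, strictly increasing, positive), the
#' differential scattering cross section per unit sample volume `intensity`
#' (cm^-1), and optionally its one-sigma uncertainty `sigma` (cm^-1, positive).
#'
#' @param q Numeric vector of scattering-vector moduli (nm^-1), strictly
#'   increasing and positive.
#' @param intensity Numeric vector of intensities (cm^-1), same length as `q`.
#' @param sigma Optional numeric vector of uncertainties (cm^-1), strictly
#'   positive, same length as `q`.
#' @return An object of class `sas_curve`: a list with elements `q`,
#'   `intensity` and `sigma` (`NULL` when absent).
#' @examples
#' sas_curve(c(0.1, 0.2), c(10, 5), c(0.1, 0.05))
#' @export
sas_curve <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) == 0L) stop("curve must contain at least one point")
  if (!all(is.finite(q)) || !all(is.finite(intensity)))
    stop("q and intensity must be finite")
  if (any(q <= 0)) stop("q must be strictly positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (length(intensity) != length(q))
    stop("intensity must have the same length as q")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must have the same length as q")
    if (!all(is.finite(sigma)) || any(sigma <= 0))
      stop("sigma entries must be finite and strictly positive")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "sas_curve")
}

#' @export
print.sas_curve <- function(x, ...) {
  cat(sprintf("<sas_curve> %d points, q in [%g, %g] nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no uncertainties" else ""))
  invisible(x)
}

#' Real-space function on a radial grid
#'
#' Holds a function of real-space distance `r` (nm), such as a projected
#' correlation function G(r) or the intermediate functions appearing in the
#' multiple-scattering formalism.
#'
#' @param r Numeric vector of distances (nm), non-negative, strictly
#'   increasing.
#' @param value Numeric vector of function values, same length as `r`.
#' @return An object of class `real_space_fn`.
#' @export
real_space_fn <- function(r, value) {
  r <- as.numeric(r); value <- as.numeric(value)
  if (length(r) == 0L) stop("empty r grid")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be finite and non-negative")
  if (any(diff(r) <= 0)) stop("r must be strictly increasing")
  if (length(value) != length(r)) stop("value must match r in length")
  structure(list(r = r, value = value), class = "real_space_fn")
}

#' @export
print.real_space_fn <- function(x, ...) {
  cat(sprintf("<real_space_fn> %d points, r in [%g, %g] nm\n",
              length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

.is_curve <- function(x) inherits(x, "sas_curve")
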