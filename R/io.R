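#' Read a scattering curve from ASCII text
#'
#' Parses whitespace- or comma-delimited text with 2 or 3 numeric columns
#' (`q`, `I`\[, `sigma`\]). Lines starting with `#` or `;` (and blank lines)
#' are skipped. Two-column files are assigned `sigma = max(0.01 I, 1e-12)`.
#'
#' @param path File path.
#' @return A [sas_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#;]|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines), "[,[:space:]]+")
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L || !(ncols %in% c(2L, 3L)))
    stop("expected 2 or 3 numeric columns")
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r), numeric(ncols)))
  bad <- which(apply(is.na(vals), 2, any))
  if (length(bad))
    stop("non-numeric value at data line ", bad[1])
  vals <- t(vals)
  q <- vals[, 1]; I <- vals[, 2]
  sigma <- if (ncols == 3L) vals[, 3] else pmax(0.01 * I, 1e-12)
  sas_curve(q, I, sigma)
}

#' Write a scattering curve as ASCII text
#'
#' Writes a 3-column table (`q`, `I`, `sigma`) with 12 significant digits and
#' a single `#` comment header carrying provenance. Curves without
#' uncertainties get a zero sigma column.
#'
#' @param curve A [sas_curve()].
#' @param path Output path.
#' @param header Provenance string placed after `#` on the first line.
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path, header = NULL) {
  stopifnot(.is_curve(curve))
  if (length(curve$q) == 0L) stop("refusing to write an empty curve")
  hdr <- sprintf("# %s", header %||%
                   sprintf("saskit %s", as.character(utils::packageVersion("saskit"))))
  sig <- curve$sigma %||% rep(0, length(curve$q))
  rows <- sprintf("%.12g %.12g %.12g", curve$q, curve$intensity, sig)
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Synthetic benchmark specification
#'
#' Defines the simulated benchmark curve used throughout: by default a
#' bimodal lognormal population of spheres with modes at 20 and 80 nm
#' (shape 0.15 each) mixed with equal volume weights, observed on 100
#' log-spaced q points in \[0.02, 2\] nm^-1 with 1% relative Gaussian noise
#' and no background. The equal-volume condition fixes the number weight of
#' the small mode at \eqn{m_2^3/(m_1^3 + m_2^3)}.
#'
#' @param distribution A `size_distribution`; default as above.
#' @param q_min,q_max,n_q Q-grid specification (nm^-1).
#' @param noise Relative Gaussian noise level, >= 0.
#' @param background Constant additive background (cm^-1).
#' @param delta_rho Sphere contrast.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(distribution = NULL, q_min = 0.02, q_max = 2,
                           n_q = 100L, noise = 0.01, background = 0,
                           delta_rho = 1) {
  stopifnot(noise >= 0, q_min > 0, q_max > q_min, n_q >= 2L)
  if (is.null(distribution)) {
    m1 <- 20; m2 <- 80; s <- 0.15
    # equal volume weights: n1 E1[V] = n2 E2[V]; same shape so w ~ 1/m^3
    w1 <- m2^3 / (m1^3 + m2^3)
    distribution <- dist_bilognormal(m1, s, m2, s, w = w1)
  }
  structure(list(distribution = distribution, q_min = q_min, q_max = q_max,
                 n_q = as.integer(n_q), noise = noise,
                 background = background, delta_rho = delta_rho),
            class = "synthetic_spec")
}

#' Simulate a benchmark scattering curve
#'
#' Evaluates the forward model
#' \eqn{I(q_i) = \int P(q_i, R)\, p(R)\, dR + b}, then perturbs each point
#' multiplicatively with seeded Gaussian noise,
#' \eqn{y_i = I_i (1 + \epsilon\, N_i(0,1))}, and reports
#' \eqn{\sigma_i = \epsilon I_i}. Negative intensities (possible at high
#' noise) are floored at a small positive epsilon and flagged via the
#' attribute `floored`. Fixed seed implies byte-identical output through
#' [write_curve()].
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer random seed.
#' @return A [sas_curve()] with attributes `truth` (noise-free intensity)
#'   and `floored`.
#' @export
simulate_curve <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  q <- exp(seq(log(spec$q_min), log(spec$q_max), length.out = spec$n_q))
  drho <- spec$delta_rho
  fwd <- integrate_over_distribution(
    function(q, R) sphere_intensity(q, R, drho), spec$distribution, q)
  I <- fwd$intensity + spec$background
  set.seed(seed)
  y <- I * (1 + spec$noise * stats::rnorm(length(I)))
  floored <- FALSE
  if (any(y <= 0)) {
    y <- pmax(y, 1e-10 * max(I))
    floored <- TRUE
  }
  sigma <- if (spec$noise > 0) spec$noise * I else pmax(0.01 * I, 1e-12)
  out <- sas_curve(q, y, sigma)
  attr(out, "truth") <- I
  attr(out, "floored") <- floored
  out
}
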