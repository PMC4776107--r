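#' Tabulated single-scattering phase function
#'
#' Container for an azimuthally symmetric phase function p(theta) on a
#' strictly increasing theta grid covering [0, pi], normalised so that the
#' integral over the full solid angle, 2 pi Int_0^pi p sin(theta) dtheta,
#' equals one.
#'
#' @param theta Angles in radians, strictly increasing, first 0, last pi.
#' @param value Non-negative per-steradian density at `theta`.
#' @param normalise Rescale `value` so the solid-angle integral is exactly
#'   one (trapezoid rule on the given grid). Set `FALSE` when the values are
#'   already exactly normalised by construction (e.g. Mie cross sections).
#' @return Object of class `phase_function`: a data.frame with columns
#'   `theta` and `value`.
#' @export
phase_function <- function(theta, value, normalise = TRUE) {
  if (length(theta) != length(value)) stop("theta and value lengths differ")
  if (length(theta) < 8) stop("grid too small")
  if (any(diff(theta) <= 0)) stop("theta must be strictly increasing")
  if (abs(theta[1]) > 1e-12 || abs(theta[length(theta)] - pi) > 1e-12)
    stop("theta grid must include the endpoints 0 and pi")
  if (any(value < 0)) stop("phase function values must be >= 0")
  if (normalise) {
    nrm <- trapz(theta, 2 * pi * value * sin(theta))
    if (nrm <= 0) stop("phase function integrates to zero")
    value <- value / nrm
  }
  structure(data.frame(theta = theta, value = value), class = c("phase_function", "data.frame"))
}

#' @export
print.phase_function <- function(x, ...) {
  cat(sprintf("phase_function: %d points, g = %.4f, p(pi) = %.4g\n",
              nrow(x), phase_anisotropy(x), x$value[nrow(x)]))
  invisible(x)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# solid-angle integral of f(theta) * p(theta), refined by cubic interpolation
# onto a dense uniform grid so coarse tabulations still integrate accurately
phase_integral <- function(pf, f, lower = 0, upper = pi, n = 20001) {
  th <- seq(lower, upper, length.out = n)
  p <- stats::spline(pf$theta, pf$value, xout = th, method = "natural")$y
  p[p < 0] <- 0
  trapz(th, 2 * pi * f(th) * p * sin(th))
}

check_normalised <- function(pf, tol = 1e-3) {
  nrm <- phase_integral(pf, function(th) 1)
  if (abs(nrm - 1) > tol)
    stop(sprintf("phase function not normalised (integral = %.6f)", nrm))
  invisible(nrm)
}

#' Anisotropy factor of a tabulated phase function
#'
#' Mean cosine of the scattering angle by quadrature on the tabulated grid.
#'
#' @param pf A [phase_function()].
#' @return g in (-1, 1).
#' @export
phase_anisotropy <- function(pf) {
  phase_integral(pf, cos)
}

#' Write / read a tabulated phase function
#'
#' Two-column whitespace-delimited text with the header line
#' `# theta_rad p`; angles in radians, values per steradian.
#'
#' @param pf A [phase_function()].
#' @param path File path.
#' @return `read_phase_function` returns a [phase_function()].
#' @export
write_phase_function <- function(pf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# theta_rad p", con)
  utils::write.table(format(pf[, c("theta", "value")], digits = 12),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phase_function
#' @export
read_phase_function <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*theta_rad\\s+p", first))
    stop("missing '# theta_rad p' header line")
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("theta", "value"))
  phase_function(d$theta, d$value, normalise = TRUE)
}
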