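#' Reflectance profile container
#'
#' A reflectance profile in either the spatial-frequency domain (intensity
#' I(q) per incident photon versus modulation frequency q, rad cm^-1) or
#' real space (reflectance density R(rho) per cm^2 versus radial distance
#' rho, cm), with a per-component breakdown. A ballistic Dirac-delta weight
#' at rho = 0 is never mixed into the grid; it is carried in the
#' `delta_weight` attribute.
#'
#' @param domain `"q"` or `"rho"`.
#' @param abscissa Non-negative, strictly increasing grid.
#' @param components Data frame (or list) of per-point component values;
#'   typically some of `saa`, `snake`, `diffuse`, `ballistic`, `total`,
#'   `stderr`.
#' @param delta_weight Scalar delta-function weight at rho = 0 (real-space
#'   profiles only).
#' @param meta Named list of provenance metadata (seed, parameters, units).
#' @param allow_negative Permit negative component values (Monte Carlo
#'   estimates carry noise); analytic profiles must be non-negative.
#' @return Object of class `reflectance_profile` (a data.frame).
#' @export
reflectance_profile <- function(domain = c("q", "rho"), abscissa, components,
                                delta_weight = 0, meta = list(),
                                allow_negative = FALSE) {
  domain <- match.arg(domain)
  if (any(diff(abscissa) <= 0) || any(abscissa < 0))
    stop("abscissa must be non-negative and strictly increasing")
  df <- as.data.frame(components)
  if (nrow(df) != length(abscissa)) stop("component length mismatch")
  # components are physical intensities; tiny negative round-off is clipped
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]]) || nm == "stderr" || allow_negative) next
    if (any(df[[nm]] < -1e-9 * max(abs(df[[nm]]), 1e-300)))
      stop(sprintf("negative values in component '%s'", nm))
    df[[nm]] <- pmax(df[[nm]], 0)
  }
  df <- cbind(stats::setNames(data.frame(abscissa), if (domain == "q") "q" else "rho"), df)
  structure(df, class = c("reflectance_profile", "data.frame"),
            domain = domain, delta_weight = delta_weight, meta = meta)
}

#' @export
print.reflectance_profile <- function(x, ...) {
  cat(sprintf("reflectance_profile [%s domain], %d points, columns: %s\n",
              attr(x, "domain"), nrow(x), paste(names(x), collapse = ", ")))
  if (attr(x, "domain") == "rho" && attr(x, "delta_weight") > 0)
    cat(sprintf("  ballistic delta weight at rho = 0: %.4g\n", attr(x, "delta_weight")))
  utils::str(attr(x, "meta"), give.attr = FALSE)
  invisible(x)
}
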