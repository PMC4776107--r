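#' Default refractive indices for the built-in sphere media
#'
#' Literature dispersion values at 0.515 um used for the polystyrene-in-water
#' test suspensions. Neither index is known to better than ~0.005 across
#' published dispersion formulas at this wavelength, so both are plain
#' arguments everywhere they are consumed and can be overridden.
#'
#' @format Named numeric vector with elements `polystyrene` and `water`.
#' @export
refl_constants <- c(polystyrene = 1.593, water = 1.333)

#' Describe a monodisperse sphere suspension
#'
#' A dilute suspension of identical spheres, the elementary scattering medium
#' for which exact Mie phase functions and bulk optical coefficients can be
#' generated. The scatterer concentration is parameterised through the target
#' scattering coefficient `mu_s` rather than a number density.
#'
#' @param diameter Sphere diameter (um).
#' @param wavelength Vacuum wavelength of the incident light (um).
#' @param n_sphere Complex refractive index of the sphere material (absolute).
#'   A positive imaginary part introduces absorption inside the spheres.
#' @param n_medium Real refractive index of the host medium.
#' @param mu_s Target scattering coefficient (cm^-1) used to scale the
#'   number density.
#' @return An object of class `sphere_suspension`.
#' @export
sphere_suspension <- function(diameter, wavelength,
                              n_sphere = complex(real = refl_constants[["polystyrene"]]),
                              n_medium = refl_constants[["water"]],
                              mu_s = 1) {
  n_sphere <- as.complex(n_sphere)
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be > 0")
  if (!is.finite(wavelength) || wavelength <= 0) stop("wavelength must be > 0")
  if (!is.finite(n_medium) || n_medium <= 0) stop("n_medium must be > 0")
  if (Im(n_sphere) < 0) stop("Im(n_sphere) must be >= 0 (passive medium)")
  if (!is.finite(mu_s) || mu_s <= 0) stop("mu_s must be > 0")
  structure(list(diameter = diameter, wavelength = wavelength,
                 n_sphere = n_sphere, n_medium = n_medium, mu_s = mu_s),
            class = "sphere_suspension")
}

#' @export
print.sphere_suspension <- function(x, ...) {
  cat(sprintf("sphere_suspension: d = %g um, lambda = %g um, n = %g%+gi, host n = %g, mu_s = %g cm^-1\n",
              x$diameter, x$wavelength, Re(x$n_sphere), Im(x$n_sphere),
              x$n_medium, x$mu_s))
  invisible(x)
}

# size parameter and relative index of a suspension
mie_x_m <- function(susp) {
  list(x = pi * susp$diameter * susp$n_medium / susp$wavelength,
       m = susp$n_sphere / susp$n_medium)
}

#' Mie partial-wave coefficients
#'
#' Computes the Mie series coefficients a_n, b_n for size parameter `x` and
#' complex relative refractive index `m` (Bohren-Huffman algorithm:
#' downward-recurrence logarithmic derivative at the internal argument,
#' upward Riccati-Bessel recurrences at the external argument).
#'
#' @param x Size parameter, pi * d * n_medium / lambda_vacuum.
#' @param m Complex relative refractive index (sphere over medium).
#' @return List with `an`, `bn` (complex vectors) and `nmax`.
#' @export
mie_coefficients <- function(x, m) {
  if (!is.finite(x) || x <= 0) stop("size parameter must be > 0")
  m <- as.complex(m)
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  nstar <- ceiling(max(nmax, Mod(mx))) + 16
  # D[k] holds the logarithmic derivative of order k-1, so the order-n value
  # sits at index n+1
  D <- rep(0 + 0i, nstar + 1)
  for (k in nstar:1) D[k] <- k / mx - 1 / (D[k + 1] + k / mx)
  n <- seq_len(nmax)
  psi <- numeric(nmax); chi <- numeric(nmax)
  psi0 <- sin(x); chi0 <- cos(x)
  psi[1] <- sin(x) / x - cos(x); chi[1] <- cos(x) / x + sin(x)
  if (nmax >= 2) {
    for (k in 2:nmax) {
      psi[k] <- (2 * k - 1) / x * psi[k - 1] - (if (k == 2) psi0 else psi[k - 2])
      chi[k] <- (2 * k - 1) / x * chi[k - 1] - (if (k == 2) chi0 else chi[k - 2])
    }
  }
  xi <- complex(real = psi, imaginary = -chi)
  psim1 <- c(psi0, psi[-nmax]); xim1 <- c(complex(real = psi0, imaginary = -chi0), xi[-nmax])
  Dn <- D[n + 1]
  an <- ((Dn / m + n / x) * psi - psim1) / ((Dn / m + n / x) * xi - xim1)
  bn <- ((Dn * m + n / x) * psi - psim1) / ((Dn * m + n / x) * xi - xim1)
  list(an = an, bn = bn, nmax = nmax)
}

#' Mie efficiencies and anisotropy from the coefficient series
#'
#' @param x Size parameter.
#' @param m Complex relative refractive index.
#' @return List with `q_sca`, `q_ext`, `q_abs`, `g` and the coefficients.
#' @export
mie_efficiencies <- function(x, m) {
  co <- mie_coefficients(x, m)
  n <- seq_len(co$nmax); an <- co$an; bn <- co$bn
  q_sca <- 2 / x^2 * sum((2 * n + 1) * (Mod(an)^2 + Mod(bn)^2))
  q_ext <- 2 / x^2 * sum((2 * n + 1) * Re(an + bn))
  i <- n[-co$nmax]
  g <- 4 / (x^2 * q_sca) *
    (sum(i * (i + 2) / (i + 1) * Re(an[i] * Conj(an[i + 1]) + bn[i] * Conj(bn[i + 1]))) +
     sum((2 * n + 1) / (n * (n + 1)) * Re(an * Conj(bn))))
  list(q_sca = q_sca, q_ext = q_ext, q_abs = q_ext - q_sca, g = g, coef = co)
}

# unpolarised scattered intensity |S1|^2/2 + |S2|^2/2 at cos(theta) = mu
mie_intensity <- function(co, mu) {
  nmu <- length(mu)
  S1 <- rep(0 + 0i, nmu); S2 <- rep(0 + 0i, nmu)
  pim1 <- rep(0, nmu); pin <- rep(1, nmu)
  for (k in seq_len(co$nmax)) {
    taun <- k * mu * pin - (k + 1) * pim1
    fn <- (2 * k + 1) / (k * (k + 1))
    S1 <- S1 + fn * (co$an[k] * pin + co$bn[k] * taun)
    S2 <- S2 + fn * (co$an[k] * taun + co$bn[k] * pin)
    pinp1 <- ((2 * k + 1) * mu * pin - (k + 1) * pim1) / k
    pim1 <- pin; pin <- pinp1
  }
  (Mod(S1)^2 + Mod(S2)^2) / 2
}

# theta grid densified near both endpoints (forward peak and backscatter)
theta_grid <- function(n_theta) {
  u <- seq(0, 1, length.out = n_theta)
  pi * (u - sin(2 * pi * u) / (2 * pi) * 0.85)
}

#' Exact Mie phase function of a sphere suspension
#'
#' Returns the azimuthally symmetric single-scattering phase function p(theta)
#' tabulated on a theta grid densified near theta = 0 and theta = pi, with the
#' normalisation 2 pi Int p(theta) sin(theta) dtheta = 1 (unit integral over
#' the full solid angle). The normalisation constant is the scattering cross
#' section from the coefficient series, so tabulated values are exact Mie
#' intensities, not renormalised by quadrature.
#'
#' @param susp A [sphere_suspension()].
#' @param n_theta Number of grid points (>= 181; default 2048).
#' @return A [phase_function()] with attributes `g` (series anisotropy) and
#'   `p_pi` (exact backscatter value p(pi)).
#' @export
mie_phase_function <- function(susp, n_theta = 2048) {
  stopifnot(inherits(susp, "sphere_suspension"))
  if (n_theta < 181) stop("n_theta must be >= 181")
  xm <- mie_x_m(susp)
  eff <- mie_efficiencies(xm$x, xm$m)
  th <- theta_grid(n_theta)
  ints <- mie_intensity(eff$coef, cos(th))
  # p = (dsigma/dOmega)/sigma_s = |S|^2/(k^2 sigma_s), and
  # sigma_s = (2 pi/k^2) Sum (2n+1)(|a_n|^2+|b_n|^2) = (pi/k^2) x^2 Qsca
  p <- ints / (pi * xm$x^2 * eff$q_sca)
  pf <- phase_function(th, p, normalise = FALSE)
  attr(pf, "g") <- eff$g
  attr(pf, "p_pi") <- unname(ints[length(ints)] / (pi * xm$x^2 * eff$q_sca))
  attr(pf, "suspension") <- susp
  pf
}

#' Bulk optical coefficients of a sphere suspension
#'
#' Scales the single-sphere Mie cross sections to the suspension number
#' density implied by the target scattering coefficient: mu_s is taken as
#' given, mu_a = mu_s * Qabs/Qsca at the same number density, the anisotropy
#' g comes from the coefficient series and the backscattering coefficient is
#' mu_b = mu_s * p(pi) with p(pi) evaluated analytically at exactly theta = pi.
#'
#' @param susp A [sphere_suspension()].
#' @param n_theta Grid size for the tabulated phase function carried along.
#' @return An [optical_properties()] object with the full tabulated phase
#'   function attached as attribute `phase`.
#' @export
mie_bulk_properties <- function(susp, n_theta = 2048) {
  stopifnot(inherits(susp, "sphere_suspension"))
  xm <- mie_x_m(susp)
  eff <- mie_efficiencies(xm$x, xm$m)
  pf <- mie_phase_function(susp, n_theta)
  saa <- map_phase(pf)
  # Qabs = Qext - Qsca is zero up to round-off for a non-absorbing sphere
  mu_a <- susp$mu_s * max(eff$q_abs, 0) / eff$q_sca
  if (eff$q_abs < -1e-8 * eff$q_sca) stop("negative absorption efficiency")
  props <- optical_properties(mu_s = susp$mu_s, mu_a = mu_a,
                              mu_b = susp$mu_s * attr(pf, "p_pi"),
                              p_b = saa$p_b, Theta = saa$Theta,
                              g = eff$g)
  attr(props, "phase") <- pf
  props
}

#' Tune sphere absorption to a target mu_a/mu_s ratio
#'
#' One-dimensional root search on Im(n_sphere) such that the bulk absorption
#' to scattering ratio of the suspension matches `target` to 1e-4 relative.
#'
#' @param susp A [sphere_suspension()].
#' @param target Target mu_a/mu_s ratio in [0, 0.2].
#' @param im_max Upper bracket for Im(n_sphere).
#' @return The suspension with Im(n_sphere) adjusted.
#' @export
tune_absorption <- function(susp, target, im_max = 0.05) {
  stopifnot(inherits(susp, "sphere_suspension"))
  if (target < 0 || target > 0.2) stop("target mu_a/mu_s must be in [0, 0.2]")
  if (target == 0) {
    susp$n_sphere <- complex(real = Re(susp$n_sphere))
    return(susp)
  }
  xm <- mie_x_m(susp)
  f <- function(im) {
    eff <- mie_efficiencies(xm$x, complex(real = Re(xm$m), imaginary = im / susp$n_medium))
    eff$q_abs / eff$q_sca - target
  }
  if (f(im_max) < 0) stop("failed to bracket the root: increase im_max")
  root <- stats::uniroot(f, c(0, im_max), tol = 1e-12)$root
  susp$n_sphere <- complex(real = Re(susp$n_sphere), imaginary = root)
  achieved <- f(root) + target
  if (abs(achieved - target) > 1e-4 * target)
    stop("root search did not reach the requested tolerance")
  susp
}
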