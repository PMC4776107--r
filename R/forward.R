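# Analytical reflectance model for a uniform semi-infinite forward-peaked
# medium at normal incidence and detection (matched boundary).
#
# Conventions used throughout:
#  * the forward lobe enters the spread function through its 2D Fourier
#    transform chi(v) = (1 - 2 p_b) exp(-v^2 Theta^2 / 4), the transform of
#    a forward lobe of 2D mean-square angular width Theta^2;
#  * the isotropic part of the phase function acts on the spread function as
#    pure loss 2 p_b mu_s (a single isotropic event removes the photon from
#    the small-angle beam);
#  * all intensities are per incident photon: I(q = 0) equals the total
#    reflectance and R(rho) integrates to it.

# scaled erfc: exp(d^2) erfc(d), stable for large d
erfcx <- function(d) {
  out <- numeric(length(d))
  small <- d < 20
  out[small] <- exp(d[small]^2) * 2 * stats::pnorm(-sqrt(2) * d[small])
  db <- d[!small]
  out[!small] <- (1 - 0.5 / db^2 + 0.75 / db^4) / (db * sqrt(pi))
  out
}

# accumulated forward-spread integral Int_0^z chi_hat(q (z - z')) dz'
# = sqrt(pi)/(q Theta) erf(q Theta z / 2); -> z as q -> 0
spread_phi <- function(q, z, Theta) {
  ifelse(q * Theta * z < 1e-8, z * (1 - (q * Theta * z)^2 / 12),
         sqrt(pi) / (q * Theta) * erf_(q * Theta * z / 2))
}

erf_ <- function(x) 2 * stats::pnorm(sqrt(2) * x) - 1

#' SAA spread function of a collimated beam
#'
#' Fraction of the collimated beam reaching depth `z` within the
#' small-angle-scattering approximation, at transverse spatial frequency
#' `q`: S(q, z) = exp(-mu_t z + mu_s (1 - 2 p_b) sqrt(pi)/(q Theta)
#' erf(q Theta z / 2)). At q = 0 only absorption and the isotropic loss
#' attenuate, S = exp(-(mu_a + 2 p_b mu_s) z); for mu_s = 0 it is the bare
#' ballistic factor exp(-mu_a z). Only normal incidence is supported.
#'
#' @param q Spatial frequency (rad cm^-1), >= 0; vectorised.
#' @param z Depth (cm), >= 0; vectorised (recycled against q).
#' @param props An [optical_properties()].
#' @param s_perp Transverse direction sine of the incident beam; only the
#'   normal-incidence value 0 is implemented.
#' @return Spread-function values in (0, 1].
#' @export
spread_function <- function(q, z, props, s_perp = 0) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(s_perp != 0)) stop("oblique incidence (s_perp != 0) is not implemented")
  if (any(z < 0)) stop("z must be >= 0")
  if (any(q < 0)) stop("q must be >= 0")
  mu_t <- props$mu_s + props$mu_a
  exp(-mu_t * z + props$mu_s * (1 - 2 * props$p_b) * spread_phi(q, z, props$Theta))
}

# attenuation constants of the three exponential kernels in the SAA depth
# integral: a_eff for the forward-route term, a_iso for the isotropic-route
# term and its ballistic subtraction
saa_attenuations <- function(props) {
  list(a_eff = 2 * (props$mu_s + props$mu_a),
       a_iso = 2 * props$mu_a + 2 * props$p_b * props$mu_s +
               2 * props$mu_s * (1 - 2 * props$p_b))
}

#' Reflectance of the SAA photons (spatial-frequency domain)
#'
#' Depth integral of the backscattering rate mu_b against the effective
#' round-trip spread functions. The first term uses the spread function of
#' an effective medium with doubled scattering and absorption (forward route
#' on both legs). The improved second term, weighted by the isotropic-route
#' probability p_iso = 2 p_b, uses a second effective medium whose isotropic
#' loss is charged once instead of twice (absorption 2 mu_a + 2 p_b mu_s),
#' with its ballistic term subtracted inside the integrand to avoid double
#' counting the unscattered path.
#'
#' @param q Spatial frequencies (rad cm^-1), vectorised.
#' @param props An [optical_properties()].
#' @param improved Include the isotropic-route second term (default TRUE);
#'   `FALSE` gives the conventional SAA.
#' @return Reflected intensity per incident photon at each q.
#' @export
reflectance_saa_q <- function(q, props, improved = TRUE) {
  stopifnot(inherits(props, "optical_properties"))
  at <- saa_attenuations(props)
  b <- 2 * props$mu_s * (1 - 2 * props$p_b)   # spread gain coefficient
  a_iso_loss <- 2 * props$mu_a + 2 * props$p_b * props$mu_s
  if (a_iso_loss <= 0 && any(q == 0))
    stop("depth integral diverges at q = 0 for a conservative medium with p_b = 0")
  z_max <- 30 / max(a_iso_loss, 1e-3 * props$mu_s)
  # integrands written with non-positive exponents only (Phi(q, z) <= z), so
  # they cannot overflow for any parameter values visited by the fitters
  vapply(q, function(qi) {
    f1 <- function(z) {
      phi <- spread_phi(qi, z, props$Theta)
      exp(-(at$a_eff - b) * z - b * (z - phi))
    }
    val <- props$mu_b * stats::integrate(f1, 0, z_max, rel.tol = 1e-8,
                                         subdivisions = 400L)$value
    if (improved && props$p_iso > 0) {
      # a_iso = a_iso_loss + b, so the integrand is the spread function of
      # the second effective medium minus its ballistic term; the weight is
      # the probability that exactly one of the entry/escape legs takes the
      # isotropic route
      f2 <- function(z) {
        phi <- spread_phi(qi, z, props$Theta)
        exp(-a_iso_loss * z - b * (z - phi)) - exp(-at$a_iso * z)
      }
      val <- val + 2 * props$p_iso * (1 - props$p_iso) * props$mu_b *
        stats::integrate(f2, 0, z_max, rel.tol = 1e-8, subdivisions = 400L)$value
    }
    val
  }, numeric(1))
}

#' High-frequency limit of the SAA reflectance
#'
#' Closed-form large-q limit. At high spatial frequency the forward-spread
#' integral saturates, erf(q Theta z / 2) -> 1, at depths far shallower
#' than the attenuation scale, so the depth integral factorises:
#' I(q) = (mu_b / 2 mu_t) [1 + e^{eps E(d)} - 1] + (isotropic-route term),
#' with eps = 2 sqrt(pi) (1 - 2 p_b) / (q l_Theta) and the finite-depth
#' damping factor E(d) = exp(d^2) erfc(d), d = 2 mu_t / (q Theta), from the
#' exponentially attenuated depth integral. The first term of the bracket
#' is the ballistic contribution, the plateau mu_b / (2 mu_t) approached
#' monotonically as q -> infinity, where the form converges to the full
#' depth integral of [reflectance_saa_q()].
#'
#' @param q Spatial frequencies (rad cm^-1), > 0.
#' @param props An [optical_properties()].
#' @param improved Include the isotropic-route term (default TRUE).
#' @return Intensity per incident photon at each q.
#' @export
reflectance_saa_highq <- function(q, props, improved = TRUE) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(q <= 0)) stop("the high-q limit form requires q > 0")
  at <- saa_attenuations(props)
  eps <- 2 * sqrt(pi) * (1 - 2 * props$p_b) * props$mu_s / (q * props$Theta)
  out <- props$mu_b / at$a_eff *
    (1 + expm1(eps * erfcx(at$a_eff / (q * props$Theta))))
  if (improved && props$p_iso > 0)
    out <- out + 2 * props$p_iso * (1 - props$p_iso) * props$mu_b *
      expm1(eps * erfcx(at$a_iso / (q * props$Theta))) / at$a_iso
  out
}

#' Ballistic plateau of the reflectance
#'
#' The q -> infinity limit mu_b / (2 mu_t): photons that backscatter once
#' and traverse both legs unscattered.
#'
#' @param props An [optical_properties()].
#' @return Scalar plateau intensity.
#' @export
ballistic_plateau <- function(props) {
  props$mu_b / (2 * (props$mu_s + props$mu_a))
}

#' Real-space SAA reflectance at close separations
#'
#' Inverse 2D Fourier (zeroth-order Hankel) transform of the high-q limit
#' form. The ballistic plateau transforms to a Dirac delta at rho = 0 whose
#' weight is returned separately and never mixed into the radial grid; the
#' continuous part is evaluated by numerical Hankel quadrature of
#' [reflectance_saa_highq()] minus the plateau.
#'
#' @param rho Radial distances (cm), > 0.
#' @param props An [optical_properties()].
#' @return List with `rho`, `value` (continuous part, per cm^2) and
#'   `delta_weight` (ballistic weight at rho = 0).
#' @export
reflectance_saa_rho_highq <- function(rho, props) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(rho <= 0)) stop("rho must be > 0 (the rho = 0 delta weight is reported separately)")
  plateau <- ballistic_plateau(props)
  f <- function(q) reflectance_saa_highq(q, props) - plateau
  val <- vapply(rho, function(r) inverse_hankel_point(f, r, q_min = 1e-9), numeric(1))
  list(rho = rho, value = val, delta_weight = plateau)
}

# --- snake and diffuse photons -------------------------------------------

#' Diffuse reflectance in the spatial-frequency domain
#'
#' Diffusion approximation with an extrapolated boundary for an isotropic
#' point source at depth z_0:
#' I_d(q) = albedo_red (e^{-kappa z_0} + e^{-kappa (z_0 + 2 z_e)}) / 2 with
#' kappa = sqrt(3 mu_a mu_t_red + q^2). The diffuse photons are those with
#' three or more large-angle scatterings in the reduced description, so the
#' equivalent source sits at the characteristic depth of the second reduced
#' scattering, z_0 = 2 l_t by default. For a conservative medium I_d -> 1
#' as q -> 0 (all photons eventually escape); the q -> 0 value agrees with
#' the standard extrapolated-boundary plane-wave diffusion reflectance for
#' the same (mu_a, mu_s_red, z_e).
#'
#' @param q Spatial frequencies (rad cm^-1), vectorised.
#' @param props An [optical_properties()].
#' @param boundary A [boundary_model()]; defaults to the matched interface.
#' @param z0 Source depth (cm); default 2 l_t.
#' @return Intensity per incident photon at each q.
#' @export
reflectance_diffuse_q <- function(q, props, boundary = boundary_model(props),
                                  z0 = NULL) {
  stopifnot(inherits(props, "optical_properties"))
  sc <- derived_scales(props)
  if (is.null(z0)) z0 <- 2 * sc$l_t
  kappa <- sqrt(3 * props$mu_a * sc$mu_t_red + q^2)
  albedo <- sc$mu_s_red / sc$mu_t_red
  albedo * (exp(-kappa * z0) + exp(-kappa * (z0 + 2 * boundary$z_e))) / 2
}

# dimensionless snake integrand machinery: all lengths in units of
# 1/mu_t_red; the snake reflectance is albedo_red^2 * Sigma(q / mu_t_red)
# with a universal shape function Sigma computed by quadrature and cached.

snake_cache <- new.env(parent = emptyenv())

# universal dimensionless snake shape Sigma(Q), interpolated from a table
# built on first use
snake_sigma <- function(Q) {
  key <- "sigma_tab"
  if (is.null(snake_cache[[key]])) {
    Qtab <- c(0, 10^seq(-2, 2.7, length.out = 70))
    sig <- vapply(Qtab, snake_sigma_direct, numeric(1))
    snake_cache[[key]] <- list(Q = Qtab, sig = sig,
                               fun = stats::splinefun(log1p(Qtab), log(pmax(sig, 1e-300)),
                                                      method = "monoH.FC"))
  }
  tab <- snake_cache[[key]]
  out <- numeric(length(Q))
  inside <- Q <= max(tab$Q)
  out[inside] <- exp(tab$fun(log1p(Q[inside])))
  if (any(!inside)) # beyond the table Sigma ~ Q^-2 tail
    out[!inside] <- tab$sig[length(tab$sig)] * (max(tab$Q) / Q[!inside])^2
  out
}

# quadrature nodes/weights for t = (node offset beyond the lower limit),
# log-graded panels resolving both the origin and the exponential tail
snake_panels <- function() {
  gl <- gauss_legendre(12)
  panels <- c(0, 10^seq(-4, log10(32), length.out = 13))
  nodes <- weights <- NULL
  for (i in seq_len(length(panels) - 1)) {
    nodes <- c(nodes, (panels[i + 1] - panels[i]) / 2 * gl$nodes +
                        (panels[i + 1] + panels[i]) / 2)
    weights <- c(weights, (panels[i + 1] - panels[i]) / 2 * gl$weights)
  }
  list(nodes = nodes, weights = weights)
}

# direct quadrature of Sigma(Q) = IntInt du1 du2 e^{-u1} K(Q,|u1-u2|) E(Q,u2)
# with the ballistic kernel K(Q,D) = (1/2) Int_D^inf dt/t e^{-t} J0(Q sqrt(t^2-D^2))
# (log-singular at D = 0) and the escape kernel
# E(Q,z) = (1/2) Int_z^inf dt z/t^2 e^{-t} J0(Q sqrt(t^2-z^2)).
# All kernels are evaluated as vectorised outer products; K is tabulated on
# a log grid in D and spline-interpolated onto |u1-u2|.
snake_sigma_direct <- function(Q) {
  tp <- snake_panels()
  # depth nodes (both u1 and u2 share the grid)
  gl <- gauss_legendre(12)
  zpan <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 28)
  zn <- zw <- NULL
  for (i in seq_len(length(zpan) - 1)) {
    zn <- c(zn, (zpan[i + 1] - zpan[i]) / 2 * gl$nodes + (zpan[i + 1] + zpan[i]) / 2)
    zw <- c(zw, (zpan[i + 1] - zpan[i]) / 2 * gl$weights)
  }
  nz <- length(zn)
  # escape kernel matrix: rows z, cols t-offset
  toff <- tp$nodes
  tmat <- outer(zn, toff, "+")
  arg <- Q * sqrt(pmax(tmat^2 - zn^2, 0))
  Evec <- 0.5 * as.vector((zn / 1) * ((exp(-tmat) / tmat^2 * besselJ(arg, 0)) %*% tp$weights))
  # K on a log D grid
  Dtab <- 10^seq(-7, log10(60), length.out = 140)
  tmatK <- outer(Dtab, toff, "+")
  argK <- Q * sqrt(pmax(tmatK^2 - Dtab^2, 0))
  Ktab <- 0.5 * as.vector((exp(-tmatK) / tmatK * besselJ(argK, 0)) %*% tp$weights)
  Kfun <- stats::splinefun(log(Dtab), Ktab, method = "natural")
  Dmat <- abs(outer(zn, zn, "-"))
  Kmat <- matrix(Kfun(log(pmax(Dmat, 1e-7))), nz, nz)
  # Sigma = sum_{ij} w_i w_j e^{-u1_i} K(|u1_i - u2_j|) E(u2_j)
  drop((zw * exp(-zn)) %*% Kmat %*% (zw * Evec))
}

#' Snake-photon reflectance in the spatial-frequency domain
#'
#' Photons with exactly two large-angle scatterings in the reduced
#' (isotropically scattering) description of the medium: ballistic entry to
#' the first reduced scattering, ballistic propagation to the second, and
#' ballistic escape, all attenuated at the reduced attenuation mu_t_red.
#' The result is albedo_red^2 Sigma(q / mu_t_red) with albedo_red =
#' mu_s_red / mu_t_red and a universal shape function Sigma evaluated by
#' quadrature (cached across calls).
#'
#' @inheritParams reflectance_diffuse_q
#' @return Intensity per incident photon at each q.
#' @export
reflectance_snake_q <- function(q, props, boundary = boundary_model(props)) {
  stopifnot(inherits(props, "optical_properties"))
  sc <- derived_scales(props)
  (sc$mu_s_red / sc$mu_t_red)^2 * snake_sigma(q / sc$mu_t_red)
}

# --- total reflectance ----------------------------------------------------

#' Locate the regime crossover frequency
#'
#' The low-frequency (snake + diffuse + ballistic) and high-frequency (SAA)
#' limits intersect at q_c ~ 2 pi beta; the actual intersection is located
#' by root bracketing around that estimate.
#'
#' @param props An [optical_properties()].
#' @param boundary A [boundary_model()].
#' @param improved Passed to [reflectance_saa_q()].
#' @return List with `q_c` and `bracketed` (FALSE when the fallback
#'   q_c = 2 pi beta was used).
#' @export
crossover_q <- function(props, boundary = boundary_model(props), improved = TRUE) {
  sc <- derived_scales(props)
  q0 <- 2 * pi * sc$beta
  f <- function(q) {
    lo <- reflectance_snake_q(q, props, boundary) +
      reflectance_diffuse_q(q, props, boundary) + ballistic_plateau(props)
    hi <- reflectance_saa_q(q, props, improved)
    log(lo) - log(hi)
  }
  lower <- q0 / 8; upper <- q0 * 8
  fl <- f(lower); fu <- f(upper)
  if (!is.finite(fl) || !is.finite(fu) || fl * fu > 0) {
    warning("low- and high-frequency branches do not intersect in the bracket; using q_c = 2 pi beta")
    return(list(q_c = q0, bracketed = FALSE))
  }
  root <- stats::uniroot(f, c(lower, upper), tol = 1e-6 * q0)
  list(q_c = root$root, bracketed = TRUE)
}

#' Total reflectance profile in the spatial-frequency domain
#'
#' The total reflectance is the sum of the contributions of the non-diffuse
#' and diffuse photons. With `split = "sum"` (default) the profile is the
#' additive decomposition SAA (one large-angle scattering) + snake (two) +
#' diffuse (three or more, diffusion from a source at the second-scattering
#' depth), which holds over the full frequency axis. With
#' `split = "piecewise"` the two limit forms are used in their respective
#' regimes — snake + diffuse + ballistic plateau below the crossover q_c,
#' the SAA expression above it — with q_c located by actual intersection of
#' the branches (bracketed around the estimate 2 pi beta).
#'
#' @param q Spatial-frequency grid spanning both regimes.
#' @param props An [optical_properties()].
#' @param boundary A [boundary_model()].
#' @param improved Passed to [reflectance_saa_q()].
#' @param split `"sum"` or `"piecewise"`.
#' @return A [reflectance_profile()] with components saa, snake, diffuse,
#'   ballistic, total and branch; `meta$q_c` holds the crossover.
#' @export
reflectance_total_q <- function(q, props, boundary = boundary_model(props),
                                improved = TRUE,
                                split = c("sum", "piecewise")) {
  stopifnot(inherits(props, "optical_properties"))
  split <- match.arg(split)
  # the additive decomposition needs no crossover; locating it costs many
  # depth integrals, so it is only done for the piecewise form
  cr <- if (split == "piecewise") crossover_q(props, boundary, improved)
        else list(q_c = 2 * pi * derived_scales(props)$beta, bracketed = NA)
  saa <- reflectance_saa_q(q, props, improved)
  snake <- reflectance_snake_q(q, props, boundary)
  diffuse <- reflectance_diffuse_q(q, props, boundary)
  ballistic <- rep(ballistic_plateau(props), length(q))
  branch <- ifelse(q < cr$q_c, "low", "high")
  total <- if (split == "sum") {
    saa + snake + diffuse
  } else {
    ifelse(branch == "low", snake + diffuse + ballistic, saa)
  }
  reflectance_profile("q", q,
                      data.frame(saa = saa, snake = snake, diffuse = diffuse,
                                 ballistic = ballistic, total = total,
                                 branch = branch),
                      meta = list(q_c = cr$q_c, bracketed = cr$bracketed,
                                  split = split, props = unclass(props)))
}
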