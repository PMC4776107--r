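#' Two-parameter SAA phase-function parameters
#'
#' The small-angle-scattering approximation (SAA) replaces an arbitrary phase
#' function by p_SAA(theta) = (1 - 2 p_b) p_Forward(theta) + p_b / (2 pi),
#' a normalised forward lobe of angular width `Theta` plus an isotropic
#' background of total weight 2 p_b. The forward lobe used throughout the
#' package is Gaussian in the chord angle,
#' p_Forward(theta) = C exp(-2 (1 - cos theta) / Theta^2),
#' which coincides with exp(-theta^2/Theta^2) near the forward direction and
#' has closed-form Legendre moments; the truncation remainder at theta = pi
#' is folded into the normalisation constant C.
#'
#' @param p_b Isotropic background weight, in [0, 0.5]. The probability of an
#'   isotropic scattering event is p_iso = 2 p_b.
#' @param Theta Root-mean-square forward scattering angle (radians), > 0.
#' @return Object of class `saa_params` with fields `p_b`, `Theta`, `p_iso`.
#' @export
saa_params <- function(p_b, Theta) {
  if (p_b < 0 || p_b > 0.5) stop("p_b must be in [0, 0.5]")
  if (p_b < 0.5 && (!is.finite(Theta) || Theta <= 0)) stop("Theta must be > 0")
  structure(list(p_b = p_b, Theta = Theta, p_iso = 2 * p_b), class = "saa_params")
}

#' @export
print.saa_params <- function(x, ...) {
  cat(sprintf("saa_params: p_b = %.4f, Theta = %.4f rad (p_iso = %.4f, g_saa = %.4f)\n",
              x$p_b, x$Theta, x$p_iso, saa_moment(x, 1)))
  invisible(x)
}

#' Isotropic background weight of a phase function
#'
#' The weight p_b is fixed by how much light the medium scatters into the
#' back hemisphere: p_b = 2 pi Int_{pi/2}^{pi} p(theta) sin(theta) dtheta.
#' For a forward-peaked phase function the Gaussian lobe contributes
#' O(e^{-2/Theta^2}) to this integral, so the back hemisphere is carried by
#' the isotropic term alone.
#'
#' @param pf A normalised [phase_function()].
#' @return p_b in [0, 0.5].
#' @export
compute_pb <- function(pf) {
  stopifnot(inherits(pf, "phase_function"))
  check_normalised(pf)
  pb <- phase_integral(pf, function(th) 1, lower = pi / 2, upper = pi)
  min(max(pb, 0), 0.5)
}

#' Forward angular width of a phase function
#'
#' The root-mean-square forward scattering angle of the mapped SAA form:
#' Theta^2 = 2 pi Int_0^pi theta^2 p(theta) sin(theta) dtheta / (1 - 2 p_b).
#' The mapping attributes the total mean-square single-scattering angle of
#' the medium to the forward lobe, so that the angular diffusion rate
#' mu_s <theta^2> of the original medium is preserved by the two-term form;
#' it is therefore not the variance of the de-floored forward peak alone.
#'
#' @param pf A normalised [phase_function()].
#' @param p_b Optional precomputed isotropic weight; computed when missing.
#' @return Theta in radians.
#' @export
compute_theta <- function(pf, p_b = NULL) {
  stopifnot(inherits(pf, "phase_function"))
  check_normalised(pf)
  if (is.null(p_b)) p_b <- compute_pb(pf)
  if (p_b >= 0.5 - 1e-6)
    stop("pure isotropic phase function: forward width undefined")
  m2 <- phase_integral(pf, function(th) th^2)
  sqrt(m2 / (1 - 2 * p_b))
}

#' Map a phase function to its SAA parameters
#'
#' @param pf A normalised [phase_function()].
#' @return An [saa_params()] object.
#' @export
map_phase <- function(pf) {
  p_b <- compute_pb(pf)
  saa_params(p_b = p_b, Theta = compute_theta(pf, p_b))
}

# normalisation constant of the chord-Gaussian forward lobe
lobe_const <- function(Theta) {
  lam <- Theta^2 / 2
  1 / (2 * pi * lam * (1 - exp(-2 / lam)))
}

# truncated-exponential moments E[s^k], s = 1 - cos(theta) ~ Exp(mean lam)
# truncated at s = 2, for the chord-Gaussian lobe
lobe_s_moment <- function(Theta, k) {
  lam <- Theta^2 / 2
  lam^k * factorial(k) * stats::pgamma(2 / lam, k + 1) / (1 - exp(-2 / lam))
}

#' Closed-form Legendre moments of the SAA phase function
#'
#' The nth Legendre moment g_n = Int P_n(cos theta) p_SAA dOmega. The
#' isotropic term contributes only at n = 0; the chord-Gaussian lobe has
#' exact moments through the truncated-exponential moments of
#' s = 1 - cos(theta). n = 1 is the anisotropy factor, equal to
#' (1 - 2 p_b)(1 - Theta^2/2) up to the O(e^{-4/Theta^2}) truncation term.
#'
#' @param params An [saa_params()].
#' @param n Moment order, integer >= 0.
#' @return The moment value; 1 for n = 0.
#' @export
saa_moment <- function(params, n) {
  stopifnot(inherits(params, "saa_params"))
  if (length(n) != 1 || n < 0 || n != round(n)) stop("n must be an integer >= 0")
  if (n == 0) return(1)
  if (params$p_b >= 0.5) return(0)
  # P_n(1 - s) = sum_k (-1)^k C(n,k) C(n+k,k) (s/2)^k
  k <- 0:n
  coef <- (-1)^k * choose(n, k) * choose(n + k, k) / 2^k
  sk <- vapply(k, function(kk) lobe_s_moment(params$Theta, kk), numeric(1))
  (1 - 2 * params$p_b) * sum(coef * sk)
}

#' Tabulate the SAA phase function
#'
#' Builds the two-term SAA phase function for given parameters on the
#' standard endpoint-densified theta grid.
#'
#' @param params An [saa_params()].
#' @param n_theta Number of grid points.
#' @return A [phase_function()].
#' @export
synthesize_saa <- function(params, n_theta = 2048) {
  stopifnot(inherits(params, "saa_params"))
  th <- theta_grid(n_theta)
  if (params$p_b >= 0.5) {
    v <- rep(1 / (4 * pi), n_theta)
  } else {
    lobe <- lobe_const(params$Theta) * exp(-2 * (1 - cos(th)) / params$Theta^2)
    v <- (1 - 2 * params$p_b) * lobe + params$p_b / (2 * pi)
  }
  phase_function(th, v, normalise = FALSE)
}
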