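#' Optical properties of a uniform scattering medium
#'
#' The complete parameter set of the reflectance model: scattering,
#' absorption and backscattering coefficients, the two SAA phase-function
#' parameters, and the anisotropy factor. Derived scales (total attenuation,
#' transport mean free path l_t, spreading length l_Theta, reduced
#' coefficients) are computed by [derived_scales()].
#'
#' @param mu_s Scattering coefficient (cm^-1), > 0.
#' @param mu_a Absorption coefficient (cm^-1), >= 0.
#' @param mu_b Backscattering coefficient mu_s * p(pi) (cm^-1), > 0.
#' @param p_b,Theta SAA parameters (see [saa_params()]).
#' @param g Anisotropy factor of the medium in [0, 1). For media built from
#'   Mie theory this is the exact series value; it generally differs from the
#'   anisotropy of the mapped SAA form (see [saa_moment()]), and both are
#'   kept — the sub-diffusive branch is driven by (p_b, Theta), the diffusive
#'   branch by g.
#' @return Object of class `optical_properties`.
#' @export
optical_properties <- function(mu_s, mu_a, mu_b, p_b, Theta, g) {
  if (mu_s <= 0) stop("mu_s must be > 0")
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_b <= 0) stop("mu_b must be > 0")
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  saa <- saa_params(p_b, Theta)
  structure(list(mu_s = mu_s, mu_a = mu_a, mu_b = mu_b,
                 p_b = saa$p_b, Theta = saa$Theta, p_iso = saa$p_iso, g = g),
            class = "optical_properties")
}

#' Derived length scales and reduced coefficients
#'
#' @param props An [optical_properties()].
#' @return List with `mu_t` (= mu_s + mu_a), `mu_s_red` (= (1-g) mu_s),
#'   `mu_t_red` (= mu_s_red + mu_a), `l_t` (= 1/mu_s_red), `l_Theta`
#'   (= Theta/mu_s), and `beta` (= mu_t_red), the inverse length scale
#'   beyond which the reflectance profile is diffusion-like; the regime
#'   crossover estimate is q_c ~ 2 pi beta.
#' @export
derived_scales <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  mu_s_red <- (1 - props$g) * props$mu_s
  list(mu_t = props$mu_s + props$mu_a,
       mu_s_red = mu_s_red,
       mu_t_red = mu_s_red + props$mu_a,
       l_t = 1 / mu_s_red,
       l_Theta = props$Theta / props$mu_s,
       beta = mu_s_red + props$mu_a)
}

#' @export
print.optical_properties <- function(x, ...) {
  sc <- derived_scales(x)
  cat(sprintf(paste0("optical_properties: mu_s = %.4g, mu_a = %.4g, mu_b = %.4g cm^-1\n",
                     "  p_b = %.4f, Theta = %.4f rad, g = %.4f\n",
                     "  l_t = %.3g cm, l_Theta = %.3g cm, beta = %.3g cm^-1\n"),
              x$mu_s, x$mu_a, x$mu_b, x$p_b, x$Theta, x$g,
              sc$l_t, sc$l_Theta, sc$beta))
  invisible(x)
}

#' Anisotropy implied by the SAA parameters
#'
#' Two conventions are exposed and kept distinct. `"moment"` is the exact
#' first Legendre moment of the mapped two-term phase function,
#' (1 - 2 p_b)(1 - Theta^2/2) up to lobe truncation — the anisotropy *of the
#' SAA form itself*. `"transport"` is the empirical connection between the
#' sub-diffusive width and the transport scale of forward-peaked media,
#' g = (1 - 2 p_b)(1 - Theta^2/4); because the mapped Theta^2 absorbs the
#' full mean-square scattering angle (see [compute_theta()]), the moment
#' convention overstates 1 - g for real forward-peaked media, and the
#' transport convention is the one used to tie the diffusive branch to
#' (p_b, Theta) during full inversion.
#'
#' @param params An [saa_params()].
#' @param relation `"transport"` (default) or `"moment"`.
#' @return Anisotropy factor.
#' @export
g_from_saa <- function(params, relation = c("transport", "moment")) {
  stopifnot(inherits(params, "saa_params"))
  relation <- match.arg(relation)
  if (relation == "moment") return(saa_moment(params, 1))
  (1 - 2 * params$p_b) * (1 - params$Theta^2 / 4)
}

#' Extrapolated-boundary model
#'
#' @param props An [optical_properties()].
#' @param matched Matched refractive index at the interface (the only
#'   supported case).
#' @param A Boundary-mismatch multiplier of the extrapolation length; 1 for
#'   a matched interface, giving the standard z_e = (2/3) l_t.
#' @return List with `z_e` (cm) and `matched`.
#' @export
boundary_model <- function(props, matched = TRUE, A = 1) {
  if (!matched) stop("index-mismatched boundaries are not supported")
  sc <- derived_scales(props)
  list(z_e = 2 / 3 * sc$l_t * A, matched = TRUE)
}
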