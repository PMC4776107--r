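#' Configure a Monte Carlo reflectance simulation
#'
#' Scalar (unpolarised) photon transport in a uniform semi-infinite medium
#' with a matched boundary: pencil beam, normal incidence at the origin,
#' implicit capture with Russian roulette, scattering angles drawn from the
#' full tabulated phase function by inverse-CDF sampling.
#'
#' @param props An [optical_properties()]; the tabulated phase function is
#'   taken from its `phase` attribute unless `phase` is given.
#' @param phase A [phase_function()] used for sampling.
#' @param n_photons Number of incident photons (>= 1e4).
#' @param seed Integer seed (applied via [set.seed()] inside [run_mc()]).
#' @param rho_edges Radial bin edges (cm), increasing.
#' @param q_grid Spatial frequencies (rad cm^-1) for the Fourier-domain
#'   tally.
#' @param weight_cutoff Roulette threshold on the photon weight.
#' @param roulette_survival Survival probability of the weight roulette.
#' @param steps_per_roulette Period of a backstop step-count roulette
#'   (survivors double their weight); 0 disables it. Conservative media do
#'   not need it: their deep walkers are terminated exactly (see
#'   `z_deep_factor`).
#' @param z_deep_factor For a conservative medium (mu_a = 0), photons
#'   deeper than `z_deep_factor` transport mean free paths are fully
#'   diffusive; their exit position is then drawn in one step from the
#'   exact half-space Brownian first-passage (Poisson) kernel instead of
#'   continuing the heavy-tailed walk. Ignored when mu_a > 0 (the weight
#'   roulette terminates those walks).
#' @param mu_exit_min Cosine cutoff of the additional near-normal Fourier
#'   tally (`I_q_normal`), the normal-detection (s_perp = 0) geometry of
#'   the analytical model; photons exiting with |cos| above the cutoff are
#'   counted.
#' @param n_batches Number of photon batches for standard errors.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(props, phase = attr(props, "phase"), n_photons = 1e6,
                      seed = 1L,
                      rho_edges = NULL, q_grid = NULL,
                      weight_cutoff = 1e-4, roulette_survival = 0.1,
                      steps_per_roulette = 0L, n_batches = 20L,
                      z_deep_factor = 10, mu_exit_min = 0.9) {
  stopifnot(inherits(props, "optical_properties"))
  if (is.null(phase)) stop("a tabulated phase function is required for sampling")
  stopifnot(inherits(phase, "phase_function"))
  check_normalised(phase)
  if (n_photons < 1e4) stop("n_photons must be >= 1e4")
  if (weight_cutoff <= 0 || weight_cutoff >= 1) stop("weight_cutoff must be in (0, 1)")
  mu_t <- props$mu_s + props$mu_a
  if (is.null(rho_edges)) rho_edges <- c(0, 10^seq(-3, log10(60 / mu_t), length.out = 81)) / 1
  if (is.null(q_grid)) q_grid <- c(0, 10^seq(log10(0.02 * mu_t), log10(60 * mu_t), length.out = 60))
  if (any(diff(rho_edges) <= 0)) stop("rho_edges must be increasing")
  structure(list(props = props, phase = phase, n_photons = as.integer(n_photons),
                 seed = as.integer(seed), rho_edges = rho_edges, q_grid = q_grid,
                 weight_cutoff = weight_cutoff, roulette_survival = roulette_survival,
                 steps_per_roulette = as.integer(steps_per_roulette),
                 n_batches = as.integer(n_batches),
                 z_deep = if (props$mu_a == 0)
                   z_deep_factor / ((1 - props$g) * props$mu_s) else Inf,
                 mu_exit_min = mu_exit_min),
            class = "mc_config")
}

# inverse CDF of the deflection angle on a uniform u grid: the CDF is the
# cumulative trapezoid of 2 pi p(theta) sin(theta) on a dense refined grid,
# inverted by monotone interpolation
phase_inverse_cdf <- function(phase, n_u = 131073, n_dense = 40001) {
  th <- seq(0, pi, length.out = n_dense)
  p <- stats::spline(phase$theta, phase$value, xout = th, method = "natural")$y
  p[p < 0] <- 0
  dens <- 2 * pi * p * sin(th)
  cdf <- c(0, cumsum((dens[-1] + dens[-n_dense]) / 2 * diff(th)))
  cdf <- cdf / cdf[n_dense]
  u <- seq(0, 1, length.out = n_u)
  # cdf is monotone non-decreasing; collapse flat stretches for approx()
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], th[keep], xout = u, rule = 2, ties = "ordered")$y
}

#' Sample scattering angles from a tabulated phase function
#'
#' Inverse-CDF draw of the polar deflection angle: u = 0 maps to theta = 0
#' and u -> 1 to theta -> pi; the sampled density is p(theta) sin(theta).
#'
#' @param phase A [phase_function()].
#' @param u Uniform variates in `[0, 1)`.
#' @return Angles in radians.
#' @export
sample_phase_angle <- function(phase, u) {
  stopifnot(inherits(phase, "phase_function"))
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  tab <- phase_inverse_cdf(phase)
  n_u <- length(tab)
  pos <- u * (n_u - 1)
  i0 <- pmin(floor(pos), n_u - 2)
  tab[i0 + 1] + (pos - i0) * (tab[i0 + 2] - tab[i0 + 1])
}

#' Run the Monte Carlo simulation
#'
#' @param config An [mc_config()].
#' @return Object of class `mc_result`: list with `R_rho` (a `"rho"`-domain
#'   [reflectance_profile()] of per-area reflectance densities with
#'   standard errors), `I_q` (a `"q"`-domain profile with standard errors),
#'   `total_reflectance`, `total_se`, and the configuration.
#' @export
run_mc <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  inv_cdf <- phase_inverse_cdf(config$phase)
  raw <- .mc_run_cpp(config$n_photons, config$props$mu_s, config$props$mu_a,
                     inv_cdf, config$rho_edges, config$q_grid,
                     config$weight_cutoff, config$roulette_survival,
                     config$steps_per_roulette, config$n_batches,
                     config$z_deep, config$mu_exit_min)
  nb <- config$n_batches
  per_batch_n <- tabulate((seq_len(config$n_photons) - 1) %% nb + 1, nb)
  # per-photon means per batch -> overall mean and SE of the mean
  comb <- function(mat) {
    means <- sweep(mat, 1, per_batch_n, "/")
    m <- colMeans(means)
    se <- apply(means, 2, stats::sd) / sqrt(nb)
    list(mean = m, se = se)
  }
  areas <- pi * diff(config$rho_edges^2)
  bins <- comb(raw$bin_batch)
  qs <- comb(raw$q_batch)
  tot <- sum(raw$total_batch) / config$n_photons
  tot_se <- stats::sd(raw$total_batch / per_batch_n) / sqrt(nb)
  centers <- sqrt((config$rho_edges[-1]^2 + config$rho_edges[-length(config$rho_edges)]^2) / 2)
  R_rho <- reflectance_profile("rho", centers,
                               data.frame(total = bins$mean / areas,
                                          stderr = bins$se / areas),
                               meta = list(seed = config$seed, kind = "mc",
                                           n_photons = config$n_photons),
                               allow_negative = TRUE)
  I_q <- reflectance_profile("q", config$q_grid,
                             data.frame(total = qs$mean, stderr = qs$se),
                             meta = list(seed = config$seed, kind = "mc",
                                         n_photons = config$n_photons),
                             allow_negative = TRUE)
  qn <- comb(raw$qn_batch)
  I_q_normal <- reflectance_profile("q", config$q_grid,
                                    data.frame(total = qn$mean, stderr = qn$se),
                                    meta = list(seed = config$seed, kind = "mc",
                                                n_photons = config$n_photons,
                                                mu_exit_min = config$mu_exit_min),
                                    allow_negative = TRUE)
  structure(list(R_rho = R_rho, I_q = I_q, I_q_normal = I_q_normal,
                 total_reflectance = tot, total_se = tot_se,
                 truncated_weight = raw$truncated_weight / config$n_photons,
                 config = config),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %g photons, total reflectance %.4f +- %.4f\n",
              x$config$n_photons, x$total_reflectance, x$total_se))
  invisible(x)
}
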