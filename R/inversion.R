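# Two-stage recovery of the optical-property set from a reflectance
# profile: stage 1 fits the dimensionless ratios mu_b/mu_s, mu_a/mu_s and
# the spreading length l_Theta = Theta/mu_s from the sub-diffusive (high-q)
# region; stage 2 fits {mu_s, mu_a, p_b, Theta} against both regimes with
# mu_b/mu_s fixed and the anisotropy tied to (p_b, Theta).

#' Merit of match between a model and a reference profile
#'
#' R^2 = 1 - sum (log I_model - log I_ref)^2 /
#'           sum (log I_ref - mean(log I_ref))^2,
#' evaluated on the common grid; 1 is a perfect match, 0 is no better than
#' the constant mean of the log reference.
#'
#' @param model,truth Either [reflectance_profile()]s sharing an abscissa,
#'   or plain numeric vectors of intensities.
#' @param component Column compared when profiles are given.
#' @return R^2 (<= 1).
#' @export
merit_r2 <- function(model, truth, component = "total") {
  pick <- function(x) {
    if (inherits(x, "reflectance_profile")) x[[component]] else as.numeric(x)
  }
  m <- pick(model); t <- pick(truth)
  if (inherits(model, "reflectance_profile") && inherits(truth, "reflectance_profile")) {
    am <- model[[1]]; at <- truth[[1]]
    if (length(am) != length(at) || any(abs(am - at) > 1e-9 * pmax(at, 1e-12)))
      stop("profiles must share a common abscissa grid")
  }
  if (length(m) != length(t)) stop("length mismatch")
  if (any(m <= 0) || any(t <= 0)) stop("merit requires strictly positive intensities")
  lt <- log(t); lm <- log(m)
  denom <- sum((lt - mean(lt))^2)
  if (denom == 0) stop("zero-variance reference")
  1 - sum((lm - lt)^2) / denom
}

# model used by stage 1, in mu_s-scaled variables: the high-q closed form
# depends only on r_b = mu_b/mu_s, r_a = mu_a/mu_s, l_Theta and p_b
highq_model <- function(q, r_b, r_a, l_Theta, p_b) {
  props <- optical_properties(mu_s = 1, mu_a = r_a, mu_b = r_b,
                              p_b = p_b, Theta = l_Theta, g = 0.9)
  reflectance_saa_highq(q, props)
}

#' Stage 1: fit the sub-diffusive ratios from high-q reflectance
#'
#' Nonlinear least squares of the high-q closed form on log reflectance
#' over q >= q_min. Recovers mu_b/mu_s, mu_a/mu_s and the spreading length
#' l_Theta = Theta/mu_s; the isotropic weight p_b only enters the closed
#' form through (1 - 2 p_b) prefactors that are degenerate with l_Theta at
#' high q, so it is held at a fixed plausible value (or a prior estimate)
#' rather than fitted.
#'
#' @param profile A `"q"`-domain [reflectance_profile()] (e.g. Monte Carlo
#'   output), `total` component.
#' @param q_min Lower edge of the fitted window. Default: the larger of
#'   2 q_c (crossover estimate from the data) and 5 mu_t-scale, chosen so
#'   the limit-form error is below the noise.
#' @param p_b Fixed isotropic weight used inside the closed form.
#' @param weights `"uniform"` or `"invvar"` (inverse variance from the
#'   profile `stderr` column when present).
#' @return List with `r_b`, `r_a`, `l_Theta`, standard errors, the window
#'   used and the `nls.lm` fit object.
#' @export
fit_highq <- function(profile, q_min = NULL, p_b = 0.02,
                      weights = c("uniform", "invvar")) {
  stopifnot(inherits(profile, "reflectance_profile"),
            attr(profile, "domain") == "q")
  weights <- match.arg(weights)
  q <- profile$q; y <- profile$total
  if (is.null(q_min)) {
    # plateau level ~ r_b/2(1+r_a); locate where the profile flattens:
    # use the largest q at which I exceeds twice the high-q median, but
    # always keep at least a dozen points in the window
    plateau <- stats::median(y[q >= 0.8 * max(q)])
    idx <- which(y > 2 * plateau)
    q_min <- if (length(idx)) q[max(idx)] else stats::quantile(q, 0.5)
    q_min <- min(q_min, q[max(1, length(q) - 11)])
  }
  sel <- q >= q_min & y > 0
  if (sum(sel) < 10) stop("fewer than 10 usable points above q_min")
  qs <- q[sel]; ys <- y[sel]
  if (max(qs) / min(qs) < 3)
    stop("high-q window too narrow for a conditioned fit (max q / min q < 3)")
  # in the sub-diffusive regime log I is a convex decreasing function of
  # log q (the slope relaxes towards the plateau); diffusive-regime data are
  # strongly concave. A concave window sits below the crossover and the
  # limit form does not apply there.
  curv <- stats::lm(log(ys) ~ stats::poly(log(qs), 2, raw = TRUE))$coefficients[3]
  if (is.finite(curv) && curv < -0.15)
    stop("window appears to lie below the crossover q_c ",
         "(log-log curvature is concave): choose a larger q_min")
  wts <- rep(1, sum(sel))
  if (weights == "invvar" && !is.null(profile$stderr)) {
    rel <- profile$stderr[sel] / ys
    wts <- 1 / pmax(rel, 1e-3)^2
    wts <- wts / mean(wts)
  }
  plateau <- stats::median(ys[qs >= 0.8 * max(qs)])
  start <- c(log_rb = log(max(plateau * 2, 1e-8)),
             log_ra = log(0.01), log_lT = log(2 / stats::median(qs)))
  resid_fun <- function(par) {
    rb <- exp(par[1]); ra <- exp(par[2]); lT <- exp(par[3])
    mod <- highq_model(qs, rb, ra, lT, p_b)
    sqrt(wts) * (log(mod) - log(ys))
  }
  fit <- minpack.lm::nls.lm(start, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- exp(fit$par)
  names(est) <- c("r_b", "r_a", "l_Theta")
  cov <- tryCatch(solve(fit$hessian) * 2 * fit$deviance / max(1, length(qs) - 3),
                  error = function(e) matrix(NA, 3, 3))
  se <- sqrt(pmax(diag(cov), 0)) * est   # delta method on the log scale
  list(r_b = unname(est[1]), r_a = unname(est[2]), l_Theta = unname(est[3]),
       se = stats::setNames(se, names(est)), q_min = q_min, p_b = p_b,
       n_points = length(qs), fit = fit,
       converged = fit$info %in% 1:4)
}

# full two-regime model on a q grid for given parameters; r_b fixed
full_model <- function(q, mu_s, mu_a, p_b, Theta, r_b,
                       g_relation = "transport") {
  g <- g_from_saa(saa_params(p_b, Theta), g_relation)
  props <- optical_properties(mu_s = mu_s, mu_a = mu_a, mu_b = r_b * mu_s,
                              p_b = p_b, Theta = Theta, g = g)
  reflectance_total_q(q, props)$total
}

#' Stage 2: fit the complete optical-property set
#'
#' Least squares on log reflectance over both regimes with mu_b/mu_s fixed
#' at the stage-1 value and the anisotropy tied to (p_b, Theta) through
#' [g_from_saa()] (the transport relation by default), which is what makes
#' mu_s identifiable from the diffusive amplitude. Free parameters:
#' mu_s, mu_a, p_b, Theta. Multi-start from jittered initialisations.
#'
#' @param profile A `"q"`-domain [reflectance_profile()] spanning both
#'   regimes.
#' @param stage1 Result of [fit_highq()].
#' @param start Optional named starting values (mu_s, mu_a, p_b, Theta).
#' @param n_starts Number of jittered starts (first start is un-jittered).
#' @param jitter_sd Log-scale jitter standard deviation.
#' @param seed Seed for the jitter.
#' @param g_relation Anisotropy tie, see [g_from_saa()].
#' @param weights `"invvar"` (default; inverse relative variance from the
#'   profile `stderr` column when present, anchoring the precisely measured
#'   diffusive amplitudes) or `"uniform"`.
#' @return Object of class `fit_result`: recovered [optical_properties()],
#'   stage-1 ratios, R^2 merit, residuals, and the crossover q_c used.
#' @export
fit_full <- function(profile, stage1, start = NULL, n_starts = 5,
                     jitter_sd = 0.15, seed = 1L,
                     g_relation = c("transport", "moment"),
                     weights = c("invvar", "uniform")) {
  stopifnot(inherits(profile, "reflectance_profile"),
            attr(profile, "domain") == "q")
  g_relation <- match.arg(g_relation)
  weights <- match.arg(weights)
  q <- profile$q; y <- profile$total
  sel <- q > 0 & y > 0
  qs <- q[sel]; ys <- y[sel]
  wts <- rep(1, length(qs))
  if (weights == "invvar" && !is.null(profile$stderr)) {
    rel <- profile$stderr[sel] / ys
    wts <- 1 / pmax(rel, 1e-4)^2
    wts <- wts / mean(wts)
  }
  r_b <- stage1$r_b
  if (is.null(start))
    start <- c(mu_s = 1 / stage1$l_Theta * 0.45, mu_a = max(stage1$r_a, 1e-4),
               p_b = stage1$p_b, Theta = 0.45)
  # bounds: mu_a >= 0, p_b in [1e-4, 0.5], Theta in (0, 1.5]
  lower <- c(log(start[["mu_s"]] / 20), log(1e-7), log(1e-4), log(1e-2))
  upper <- c(log(start[["mu_s"]] * 20), log(0.2 * start[["mu_s"]] * 20), log(0.5), log(1.5))
  resid_fun <- function(par) {
    mu_s <- exp(par[1]); mu_a <- exp(par[2]); p_b <- exp(par[3]); Theta <- exp(par[4])
    mod <- tryCatch(full_model(qs, mu_s, mu_a, p_b, Theta, r_b, g_relation),
                    error = function(e) NULL)
    if (is.null(mod) || any(!is.finite(mod)) || any(mod <= 0))
      return(rep(1e3, length(qs)))
    sqrt(wts) * (log(mod) - log(ys))
  }
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    p0 <- log(unlist(start))
    if (k > 1) p0 <- p0 + stats::rnorm(4, 0, jitter_sd)
    p0 <- pmin(pmax(p0, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fun, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) stop("stage-2 fit failed from all starts")
  pb <- unname(exp(best$par))
  mu_s <- pb[1]; mu_a <- pb[2]; p_b <- pb[3]; Theta <- pb[4]
  at_bound <- (abs(best$par - lower) < 1e-3) | (abs(best$par - upper) < 1e-3)
  if (any(at_bound))
    warning("parameters pinned at bounds: ",
            paste(c("mu_s", "mu_a", "p_b", "Theta")[at_bound], collapse = ", "))
  g <- g_from_saa(saa_params(p_b, Theta), g_relation)
  props <- optical_properties(mu_s = mu_s, mu_a = mu_a, mu_b = r_b * mu_s,
                              p_b = p_b, Theta = Theta, g = g)
  mod <- full_model(qs, mu_s, mu_a, p_b, Theta, r_b, g_relation)
  r2 <- merit_r2(mod, ys)
  cr <- crossover_q(props)
  structure(list(params = props, stage1 = stage1, r_squared = r2,
                 residuals = log(mod) - log(ys), q = qs,
                 regime_split = cr$q_c, g_relation = g_relation,
                 converged = best$info %in% 1:4, fit = best),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("fit_result: R^2 = %.4f (q_c = %.3g)\n",
                     "  mu_s = %.4g, mu_a = %.4g, mu_b = %.4g cm^-1\n",
                     "  p_b = %.4f, Theta = %.4f, g = %.4f [%s relation]\n"),
              x$r_squared, x$regime_split, p$mu_s, p$mu_a, p$mu_b,
              p$p_b, p$Theta, p$g, x$g_relation))
  invisible(x)
}
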