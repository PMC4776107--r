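# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (cached); used by the quadrature helpers across the package.
gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    k <- seq_len(n - 1)
    off <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- off; J[cbind(k + 1, k)] <- off
    e <- eigen(J, symmetric = TRUE)
    gl_cache[[key]] <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  }
  gl_cache[[key]]
}

# Int_a^b f(q) J0(q rho) q dq by Gauss-Legendre panels split at the Bessel
# zeros of J0(q rho), so each panel holds at most one oscillation lobe
bessel_panels <- function(a, b, rho, max_panels = 4000) {
  # split at the Bessel zeros (at most one oscillation lobe per panel) and
  # additionally on a log-spaced grid so that sharp low-frequency structure
  # of the transformed function is resolved even when the lobes are wide
  cuts <- if (rho > 0) {
    j0 <- besselJ_zeros(max_panels) / rho
    j0[j0 > a & j0 < b]
  } else numeric(0)
  lo <- max(a, b * 1e-5)
  extra <- 10^seq(log10(lo), log10(b), length.out = 48)
  sort(unique(c(a, cuts, extra[extra > a & extra < b], b)))
}

bz_cache <- new.env(parent = emptyenv())
besselJ_zeros <- function(n) {
  if (is.null(bz_cache$z) || length(bz_cache$z) < n) {
    # McMahon expansion, refined by Newton steps on J0
    k <- seq_len(n)
    x <- (k - 0.25) * pi
    x <- x + 1 / (8 * x) - 31 / (384 * x^3)
    for (i in 1:3) x <- x + besselJ(x, 0) / besselJ(x, 1)
    bz_cache$z <- x
  }
  bz_cache$z[seq_len(n)]
}

# single-point inverse 2D Fourier transform of an isotropic function:
# (1/2pi) Int f(q) J0(q rho) q dq
inverse_hankel_point <- function(f, rho, q_min = 0, q_max = Inf, n_gl = 24,
                                 tail_tol = 1e-8) {
  gl <- gauss_legendre(n_gl)
  if (!is.finite(q_max)) {
    # integrate lobe by lobe; the series over Bessel lobes is alternating
    # and may converge only conditionally, so the tail is resummed by
    # repeated averaging of the partial sums (Euler transformation)
    n_lobes <- 320
    edges <- c(q_min, besselJ_zeros(n_lobes) / max(rho, 1e-12))
    edges <- edges[edges >= q_min]
    pieces <- numeric(length(edges) - 1)
    for (i in seq_len(length(edges) - 1)) {
      x <- (edges[i + 1] - edges[i]) / 2 * gl$nodes + (edges[i + 1] + edges[i]) / 2
      w <- (edges[i + 1] - edges[i]) / 2 * gl$weights
      pieces[i] <- sum(w * f(x) * besselJ(x * rho, 0) * x)
      if (i > 12 && all(abs(pieces[(i - 3):i]) <
                        tail_tol * max(abs(sum(pieces)), 1e-300))) {
        pieces <- pieces[1:i]
        break
      }
    }
    ps <- cumsum(pieces)
    m <- min(40, length(ps))
    x <- ps[(length(ps) - m + 1):length(ps)]
    while (length(x) > 1) x <- (x[-1] + x[-length(x)]) / 2
    return(x / (2 * pi))
  }
  edges <- bessel_panels(q_min, q_max, rho)
  total <- 0
  for (i in seq_len(length(edges) - 1)) {
    x <- (edges[i + 1] - edges[i]) / 2 * gl$nodes + (edges[i + 1] + edges[i]) / 2
    w <- (edges[i + 1] - edges[i]) / 2 * gl$weights
    total <- total + sum(w * f(x) * besselJ(x * rho, 0) * x)
  }
  total / (2 * pi)
}

# forward 2D Fourier transform of an isotropic real-space function:
# Int f(rho) J0(q rho) 2 pi rho drho
forward_hankel_point <- function(f, q, rho_max, n_gl = 24) {
  gl <- gauss_legendre(n_gl)
  edges <- bessel_panels(0, rho_max, q)
  total <- 0
  for (i in seq_len(length(edges) - 1)) {
    x <- (edges[i + 1] - edges[i]) / 2 * gl$nodes + (edges[i + 1] + edges[i]) / 2
    w <- (edges[i + 1] - edges[i]) / 2 * gl$weights
    total <- total + sum(w * f(x) * besselJ(x * q, 0) * x)
  }
  2 * pi * total
}

#' Transform a spatial-frequency profile to real space
#'
#' Zeroth-order Hankel (inverse 2D Fourier) transform of each component of
#' a spatial-frequency reflectance profile onto a radial grid. The ballistic
#' plateau (the q -> infinity limit of the total) transforms to a Dirac
#' delta at rho = 0: it is subtracted before the quadrature and carried as
#' the `delta_weight` attribute of the result. The profile is interpolated
#' by cubic splines between grid points; beyond the tabulated q_max the
#' (plateau-subtracted) integrand is assumed zero, and the magnitude of the
#' last retained Bessel lobe provides a truncation-error estimate.
#'
#' @param profile A `"q"`-domain [reflectance_profile()].
#' @param rho Radial grid (cm), > 0.
#' @param components Which columns to transform (default `"total"`).
#' @param q_max_factor Error if q_max < this multiple of mu_t when the
#'   profile metadata carries optical properties (guards against truncation).
#' @return A `"rho"`-domain [reflectance_profile()].
#' @export
to_real_space <- function(profile, rho, components = "total", q_max_factor = 50) {
  stopifnot(inherits(profile, "reflectance_profile"),
            attr(profile, "domain") == "q")
  if (any(rho <= 0)) stop("rho grid must be > 0")
  q <- profile$q
  meta <- attr(profile, "meta")
  if (!is.null(meta$props)) {
    mu_t <- meta$props$mu_s + meta$props$mu_a
    if (max(q) < q_max_factor * mu_t)
      stop(sprintf("q grid reaches only %.3g; need q_max >= %g mu_t = %.3g for a controlled transform",
                   max(q), q_max_factor, q_max_factor * mu_t))
  }
  out <- list()
  trunc_err <- 0
  for (comp in components) {
    y <- profile[[comp]]
    if (is.null(y)) stop(sprintf("no component '%s'", comp))
    plateau <- 0
    if (comp %in% c("total", "saa", "ballistic")) {
      # subtract the ballistic plateau (as a Dirac weight) only when the
      # tail has actually flattened; profiles without a plateau (diffuse,
      # snake) keep their full tail in the quadrature
      tail_y <- y[q >= 0.5 * max(q)]
      flat <- (max(tail_y) - min(tail_y)) / stats::median(tail_y)
      if (is.finite(flat) && flat < 0.35)
        plateau <- stats::median(utils::tail(y, 3))
    }
    sf <- stats::splinefun(q, y - plateau, method = "natural")
    f <- function(qq) ifelse(qq <= max(q), sf(qq), 0)
    vals <- vapply(rho, function(r)
      inverse_hankel_point(f, r, q_min = min(q), q_max = max(q)), numeric(1))
    out[[comp]] <- vals
    trunc_err <- max(trunc_err, abs(y[length(y)] - plateau) * max(q) / (2 * pi))
    attr(out, paste0("delta_", comp)) <- plateau
  }
  dw <- if ("total" %in% components)
    stats::median(utils::tail(profile$total, 3)) else 0
  # tiny negative ringing from the truncated quadrature is legitimate
  # transform output
  reflectance_profile("rho", rho, out, delta_weight = dw,
                      meta = c(meta, list(truncation_scale = trunc_err)),
                      allow_negative = TRUE)
}
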