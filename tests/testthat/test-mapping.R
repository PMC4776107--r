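legendre_pn <- function(n, x) {
  if (n == 0) return(1)
  if (n == 1) return(x)
  pm1 <- 1; p <- x
  for (k in 2:n) {
    pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    pm1 <- p; p <- pn
  }
  p
}

test_that("an isotropic phase function maps to the pure-isotropic limit", {
  th <- seq(0, pi, length.out = 512)
  iso <- phase_function(th, rep(1 / (4 * pi), 512), normalise = FALSE)
  expect_equal(compute_pb(iso), 0.5, tolerance = 1e-6)
  expect_error(compute_theta(iso), "isotropic")
})

test_that("synthesized SAA phase functions are normalised and round-trip p_b", {
  for (pars in list(saa_params(0.0177, 0.451), saa_params(0.05, 0.3),
                    saa_params(0.2, 0.6), saa_params(0.001, 0.15))) {
    pf <- synthesize_saa(pars, 2048)
    expect_lt(abs(reflphase:::phase_integral(pf, function(th) 1) - 1), 1e-5)
    # the remapped weight exceeds p_b by exactly the (1 - 2 p_b)-weighted
    # back-hemisphere mass of the truncated lobe — closed form in
    # s = 1 - cos(theta)
    lam <- pars$Theta^2 / 2
    tail_mass <- (exp(-1 / lam) - exp(-2 / lam)) / (1 - exp(-2 / lam))
    expect_lt(abs(compute_pb(pf) - pars$p_b - (1 - 2 * pars$p_b) * tail_mass),
              1e-4)
  }
  # pure isotropic limit: flat at 1/(4 pi)
  flat <- synthesize_saa(saa_params(0.5, 1), 256)
  expect_equal(range(flat$value), rep(1 / (4 * pi), 2), tolerance = 1e-12)
})

test_that("the mapped width absorbs the isotropic second moment by design", {
  # the forward-width integral assigns the *total* mean-square scattering
  # angle to the lobe; on a synthesized SAA input the remapped width must
  # therefore equal the closed combination of lobe and isotropic moments,
  # not the input width itself
  pars <- saa_params(0.0177, 0.451)
  pf <- synthesize_saa(pars, 4096)
  Theta_out <- compute_theta(pf)
  th <- seq(0, pi, length.out = 200001)
  lobe <- reflphase:::lobe_const(pars$Theta) * exp(-2 * (1 - cos(th)) / pars$Theta^2)
  m2_lobe <- reflphase:::trapz(th, 2 * pi * th^2 * lobe * sin(th))
  m2_iso <- (pi^2 - 4) / 2   # solid-angle average of theta^2
  expected <- sqrt(((1 - 2 * pars$p_b) * m2_lobe + 2 * pars$p_b * m2_iso) /
                   (1 - 2 * pars$p_b))
  expect_equal(Theta_out, expected, tolerance = 1e-4)
  expect_gt(Theta_out, pars$Theta)  # the isotropic term widens the map
})

test_that("closed-form SAA moments agree with quadrature for n <= 4", {
  for (pars in list(saa_params(0.0177, 0.451), saa_params(0.1, 0.8),
                    saa_params(0.02, 0.2))) {
    pf <- synthesize_saa(pars, 8192)
    for (n in 0:4) {
      quad <- reflphase:::phase_integral(
        pf, function(th) vapply(cos(th), function(m) legendre_pn(n, m), numeric(1)))
      expect_equal(saa_moment(pars, n), quad, tolerance = 1e-4,
                   label = sprintf("moment n=%d pb=%g Th=%g", n, pars$p_b, pars$Theta))
    }
  }
})

test_that("anisotropy moment has the stated closed behaviour", {
  expect_identical(saa_moment(saa_params(0.1, 0.5), 0), 1)
  # delta-function limit: pure forward, no spread
  expect_equal(saa_moment(saa_params(0, 1e-3), 1), 1, tolerance = 1e-5)
  # g = (1 - 2 p_b)(1 - Theta^2/2) to lobe-truncation accuracy
  pars <- saa_params(0.0177, 0.451)
  expect_equal(saa_moment(pars, 1),
               (1 - 2 * pars$p_b) * (1 - pars$Theta^2 / 2), tolerance = 1e-8)
  expect_error(saa_moment(pars, -1), "integer")
})

test_that("the forward width shrinks from the small to the large sphere", {
  # the qualitative trend for Mie scatterers, checked on the two reference
  # suspensions; the trend is not strictly monotone across the whole
  # Mie-ringing regime (see the methods vignette)
  expect_gt(case_props("d049")$Theta, case_props("d150")$Theta)
  Theta_mid <- map_phase(mie_phase_function(sphere_suspension(0.8, 0.515), 1024))$Theta
  expect_gt(case_props("d049")$Theta, Theta_mid)
  expect_gt(Theta_mid, case_props("d150")$Theta * 0.95)
})

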