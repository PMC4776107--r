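test_that("Mie efficiencies reproduce classic benchmark values", {
  # canonical test case x = 10, m = 1.5: Qext = 2.8820 (Wiscombe's MIEV0)
  eff <- mie_efficiencies(10, 1.5 + 0i)
  expect_equal(eff$q_ext, 2.8820, tolerance = 1e-4)
  expect_equal(eff$q_sca, eff$q_ext, tolerance = 1e-12)  # non-absorbing
  # Rayleigh limit: Qsca -> (8/3) x^4 |(m^2-1)/(m^2+2)|^2, g -> 0
  x <- 0.01; m <- 1.2
  eff <- mie_efficiencies(x, m)
  expect_equal(eff$q_sca, 8 / 3 * x^4 * Mod((m^2 - 1) / (m^2 + 2))^2,
               tolerance = 1e-4)
  expect_lt(abs(eff$g), 1e-3)
})

test_that("Rayleigh-limit phase function has the 1 + cos^2 shape", {
  susp <- sphere_suspension(0.004, 0.515)
  pf <- mie_phase_function(susp, n_theta = 512)
  shape <- (1 + cos(pf$theta)^2)
  shape <- shape / reflphase:::trapz(pf$theta, 2 * pi * shape * sin(pf$theta))
  expect_lt(max(abs(pf$value - shape) / max(shape)), 1e-3)
})

test_that("phase functions are normalised and match the series anisotropy", {
  for (name in c("d150", "d049")) {
    pf <- attr(case_props(name), "phase")
    nrm <- reflphase:::phase_integral(pf, function(th) 1)
    expect_lt(abs(nrm - 1), 1e-6)
    expect_lt(abs(phase_anisotropy(pf) - attr(pf, "g")), 1e-4)
  }
})

test_that("backscatter coefficient equals the tabulated phase function at pi", {
  p <- case_props("d150")
  pf <- attr(p, "phase")
  # grid value at theta = pi vs the analytic series value used for mu_b
  expect_equal(p$mu_b / p$mu_s, pf$value[nrow(pf)], tolerance = 1e-10)
  # spline interpolation near pi agrees with the endpoint to ~1e-3
  sp <- stats::spline(pf$theta, pf$value, xout = pi - 1e-4)$y
  expect_equal(sp, p$mu_b / p$mu_s, tolerance = 2e-3)
})

test_that("non-physical suspensions are rejected", {
  expect_error(sphere_suspension(-1, 0.515), "diameter")
  expect_error(sphere_suspension(1.5, 0.515, n_medium = -1), "n_medium")
  expect_error(sphere_suspension(1.5, 0.515, n_sphere = 1.59 - 0.1i), "Im")
  expect_error(mie_phase_function(sphere_suspension(1.5, 0.515), n_theta = 100),
               "n_theta")
})

test_that("absorption tuning hits the target ratio and is monotone", {
  susp <- tune_absorption(sphere_suspension(1.50, 0.515), 0.0130)
  p <- mie_bulk_properties(susp)
  expect_equal(p$mu_a / p$mu_s, 0.0130, tolerance = 1e-4)
  # untouched when the target is zero
  s0 <- tune_absorption(sphere_suspension(1.50, 0.515), 0)
  expect_identical(Im(s0$n_sphere), 0)
  expect_equal(mie_bulk_properties(s0)$mu_a, 0)
  # mu_a/mu_s strictly increasing in Im(n) over the bracket
  xm <- reflphase:::mie_x_m(susp)
  ratios <- vapply(c(5e-4, 1e-3, 2e-3, 4e-3), function(im) {
    eff <- mie_efficiencies(xm$x, complex(real = Re(xm$m), imaginary = im / susp$n_medium))
    eff$q_abs / eff$q_sca
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})
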