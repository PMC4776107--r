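test_that("identical configuration and seed give identical tallies", {
  p <- case_props("d150")
  cfg <- mc_config(p, n_photons = 1e4, seed = 11)
  a <- run_mc(cfg); b <- run_mc(cfg)
  expect_identical(a$I_q$total, b$I_q$total)
  expect_identical(a$R_rho$total, b$R_rho$total)
  expect_identical(a$total_reflectance, b$total_reflectance)
})

test_that("a conservative half space returns every photon", {
  res <- case_mc("d150")
  expect_lt(abs(res$total_reflectance - 1), max(3 * res$total_se, 1e-12))
  # the Fourier tally at q = 0 equals the total reflectance
  expect_equal(res$I_q$total[1], res$total_reflectance, tolerance = 1e-8)
})

test_that("absorbing isotropic medium matches an independent-sampler oracle", {
  albedo <- 0.9
  th <- seq(0, pi, length.out = 1024)
  iso <- phase_function(th, rep(1 / (4 * pi), 1024), normalise = FALSE)
  props <- optical_properties(mu_s = albedo, mu_a = 1 - albedo, mu_b = albedo / (4 * pi),
                              p_b = 0.499, Theta = 1.0, g = 0)
  res <- run_mc(mc_config(props, phase = iso, n_photons = 1e5, seed = 3))
  oracle <- iso_albedo_oracle(albedo, n = 6e4, seed = 5)
  se <- sqrt(oracle * (1 - oracle) / 6e4) + res$total_se
  expect_lt(abs(res$total_reflectance - oracle), 4 * se)
})

test_that("inverse-CDF angle sampling reproduces the phase function", {
  pf <- attr(case_props("d150"), "phase")
  expect_equal(sample_phase_angle(pf, 0), 0, tolerance = 1e-9)
  expect_equal(sample_phase_angle(pf, 1), pi, tolerance = 1e-9)
  set.seed(21)
  th <- sample_phase_angle(pf, runif(2e5))
  g_hat <- mean(cos(th))
  se <- stats::sd(cos(th)) / sqrt(length(th))
  expect_lt(abs(g_hat - attr(pf, "g")), 3 * se)
  # isotropic input: cos(theta) uniform on [-1, 1]
  th0 <- seq(0, pi, length.out = 512)
  iso <- phase_function(th0, rep(1 / (4 * pi), 512), normalise = FALSE)
  u <- sample_phase_angle(iso, runif(4e4))
  ks <- suppressWarnings(stats::ks.test(cos(u), "punif", -1, 1))
  expect_gt(ks$p.value, 1e-4)
})

test_that("standard errors scale as one over the square root of n", {
  p <- case_props("d150abs")
  pick <- function(n, seed) {
    res <- run_mc(mc_config(p, n_photons = n, seed = seed, n_batches = 100L))
    # average relative SE over well-populated frequencies
    sel <- which(res$I_q$total > 0.01)
    mean(res$I_q$stderr[sel] / res$I_q$total[sel])
  }
  r1 <- pick(1.6e5, 8)
  r2 <- pick(8e4, 9)
  expect_lt(abs(r2 / r1 - sqrt(2)), 0.1 * sqrt(2))
})

test_that("invalid configurations are rejected", {
  p <- case_props("d150")
  expect_error(mc_config(p, n_photons = 100), "n_photons")
  expect_error(mc_config(p, weight_cutoff = 2), "weight_cutoff")
  expect_error(mc_config(p, rho_edges = c(1, 0.5)), "increasing")
})
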