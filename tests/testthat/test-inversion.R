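test_that("merit of match reproduces its defining cases", {
  expect_equal(merit_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  truth <- c(0.5, 2, 8, 1)
  const <- rep(exp(mean(log(truth))), 4)
  expect_equal(merit_r2(const, truth), 0, tolerance = 1e-12)
  # hand-sized check against independent arithmetic
  model <- c(0.6, 1.8, 7.0, 1.3)
  lt <- log(truth); lm <- log(model)
  byhand <- 1 - sum((lm - lt)^2) / sum((lt - mean(lt))^2)
  expect_equal(merit_r2(model, truth), byhand)
  expect_error(merit_r2(c(1, -1), c(1, 1)), "positive")
  expect_error(merit_r2(c(1, 2), c(3, 3)), "zero-variance")
})

test_that("stage 1 recovers its own closed form exactly", {
  props <- optical_properties(1, 0.01, 0.004, 0.02, 0.5, 0.9)
  qs <- 10^seq(log10(3), log10(40), length.out = 40)
  prof <- reflectance_profile("q", qs,
                              data.frame(total = reflectance_saa_highq(qs, props)))
  s1 <- fit_highq(prof, q_min = 3, p_b = 0.02)
  expect_true(s1$converged)
  expect_equal(s1$r_b, 0.004, tolerance = 1e-6)
  expect_equal(s1$r_a, 0.01, tolerance = 1e-4)
  expect_equal(s1$l_Theta, 0.5, tolerance = 1e-6)
})

test_that("stage 1 rejects windows below the crossover or too narrow", {
  props <- toy_props()
  # diffusive-only window: steep exponential decay, not the limit form
  qs <- 10^seq(-2, log10(0.4), length.out = 30)
  prof <- reflectance_total_q(qs, props)
  expect_error(fit_highq(prof, q_min = min(qs)), "below the crossover")
  # too-narrow window
  qs2 <- seq(5, 9, length.out = 15)
  prof2 <- reflectance_profile("q", qs2,
                               data.frame(total = reflectance_saa_highq(qs2, props)))
  expect_error(fit_highq(prof2, q_min = 5), "narrow")
})

test_that("noise-free full inversion recovers all free parameters", {
  set.seed(14)
  for (k in 1:6) {
    pb <- runif(1, 0.01, 0.05); Th <- runif(1, 0.3, 0.7)
    mu_s <- runif(1, 0.5, 2); mu_a <- runif(1, 0, 0.03) * mu_s
    mu_b <- runif(1, 0.002, 0.01) * mu_s
    g <- g_from_saa(saa_params(pb, Th), "transport")
    props <- optical_properties(mu_s, mu_a, mu_b, pb, Th, g)
    mu_t <- mu_s + mu_a
    q <- 10^seq(log10(0.02 * mu_t), log10(8 * mu_t), length.out = 45)
    prof <- reflectance_total_q(q, props)
    s1 <- list(r_b = mu_b / mu_s, r_a = mu_a / mu_s, l_Theta = Th / mu_s, p_b = pb)
    fr <- fit_full(prof, s1, seed = k, n_starts = 2)
    v <- fr$params
    expect_equal(v$mu_s, mu_s, tolerance = 1e-3)
    expect_equal(v$mu_a, mu_a, tolerance = max(1e-3 * mu_a, 1e-6))
    expect_equal(v$p_b, pb, tolerance = 1e-3)
    expect_equal(v$Theta, Th, tolerance = 1e-3)
  }
})

test_that("inversion is robust to one percent multiplicative noise", {
  set.seed(5)
  errs <- matrix(NA, 8, 2)
  for (k in 1:8) {
    pb <- runif(1, 0.01, 0.05); Th <- runif(1, 0.3, 0.7)
    mu_s <- runif(1, 0.5, 2); mu_a <- runif(1, 0, 0.03) * mu_s
    mu_b <- runif(1, 0.002, 0.01) * mu_s
    g <- g_from_saa(saa_params(pb, Th), "transport")
    props <- optical_properties(mu_s, mu_a, mu_b, pb, Th, g)
    mu_t <- mu_s + mu_a
    q <- 10^seq(log10(0.02 * mu_t), log10(8 * mu_t), length.out = 45)
    prof <- reflectance_total_q(q, props)
    noisy <- reflectance_profile("q", q,
               data.frame(total = prof$total * exp(rnorm(length(q), 0, 0.01))))
    s1 <- list(r_b = mu_b / mu_s, r_a = mu_a / mu_s, l_Theta = Th / mu_s, p_b = pb)
    fr <- fit_full(noisy, s1, seed = k, n_starts = 2)
    errs[k, ] <- abs(c(fr$params$Theta / Th, fr$params$mu_s / mu_s) - 1)
  }
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("fixing the stage-1 backscatter ratio does not hurt at the truth", {
  pb <- 0.02; Th <- 0.45; mu_s <- 1; mu_a <- 0.01; mu_b <- 0.0035
  g <- g_from_saa(saa_params(pb, Th), "transport")
  props <- optical_properties(mu_s, mu_a, mu_b, pb, Th, g)
  q <- 10^seq(log10(0.02), log10(8), length.out = 40)
  prof <- reflectance_total_q(q, props)
  s1_true <- list(r_b = mu_b, r_a = mu_a, l_Theta = Th, p_b = pb)
  s1_off <- within(s1_true, r_b <- r_b * 1.05)
  f_true <- fit_full(prof, s1_true, seed = 1, n_starts = 2)
  f_off <- suppressWarnings(fit_full(prof, s1_off, seed = 1, n_starts = 2))
  expect_lte(f_true$fit$deviance, f_off$fit$deviance + 1e-12)
})
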