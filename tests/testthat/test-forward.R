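test_that("spread function obeys its limiting identities", {
  p <- toy_props()
  z <- c(0.1, 0.7, 3)
  # q = 0: only absorption and isotropic loss attenuate
  expect_equal(spread_function(0, z, p),
               exp(-(p$mu_a + 2 * p$p_b * p$mu_s) * z), tolerance = 1e-12)
  # mu_s = 0: pure ballistic
  p0 <- optical_properties(1e-12, 0.3, 1e-13, 0.02, 0.45, 0.9)
  expect_equal(spread_function(2, z, p0), exp(-0.3 * z), tolerance = 1e-9)
  expect_error(spread_function(1, -0.1, p), "z")
  expect_error(spread_function(1, 1, p, s_perp = 0.1), "oblique")
})

test_that("closed-form spread agrees with the direct depth integral", {
  p <- toy_props()
  for (q in c(0.3, 2, 15)) for (z in c(0.2, 1.5, 4)) {
    phi <- stats::integrate(function(u) exp(-q^2 * p$Theta^2 * u^2 / 4), 0, z,
                            rel.tol = 1e-12)$value
    direct <- exp(-(p$mu_s + p$mu_a) * z + p$mu_s * (1 - 2 * p$p_b) * phi)
    expect_equal(spread_function(q, z, p), direct, tolerance = 1e-6)
  }
})

test_that("SAA reflectance has the stated limits", {
  # mu_s -> 0: bare ballistic return mu_b / (2 mu_a)
  p0 <- optical_properties(1e-8, 0.05, 0.001, 0.02, 0.45, 0.9)
  expect_equal(reflectance_saa_q(3, p0), 0.001 / (2 * 0.05), tolerance = 1e-6)
  # conservative medium with no isotropic background diverges at q = 0
  pdiv <- optical_properties(1, 0, 0.003, 0, 0.45, 0.9)
  expect_error(reflectance_saa_q(c(0, 1), pdiv), "diverges")
  # large q: convergence to the closed-form limit within 1%
  p <- toy_props()
  lT <- p$Theta / p$mu_s
  qs <- c(20, 30, 60) / lT
  expect_lt(max(abs(reflectance_saa_highq(qs, p) / reflectance_saa_q(qs, p) - 1)),
            0.01)
  expect_error(reflectance_saa_highq(0, p), "q > 0")
})

test_that("high-q form approaches the ballistic plateau monotonically", {
  p <- toy_props()
  qs <- 10^seq(1, 4, length.out = 40)
  v <- reflectance_saa_highq(qs, p)
  expect_true(all(diff(v) < 0))
  expect_equal(v[40], ballistic_plateau(p), tolerance = 1e-3)
})

test_that("all components are non-negative over the physical box", {
  set.seed(7)
  qs <- 10^seq(-2, 2, length.out = 25)
  for (k in 1:8) {
    g <- runif(1, 0.7, 0.98)
    pb <- runif(1, 0.005, 0.1)
    Th <- runif(1, 0.2, 1.0)
    mua <- runif(1, 0, 0.05)
    p <- optical_properties(1, mua, 0.003, pb, Th, g)
    prof <- reflectance_total_q(qs, p)
    expect_true(all(prof$saa >= 0 & prof$snake >= 0 & prof$diffuse >= 0 &
                    prof$total >= 0))
  }
})

test_that("dimensionless profiles are invariant under the mu_s scale", {
  # lengths in units of 1/mu_s: scaling mu_s by c and q by c leaves
  # I(q) unchanged when all ratios are held fixed
  p1 <- optical_properties(1, 0.01, 0.004, 0.02, 0.5, 0.92)
  p2 <- optical_properties(5, 0.05, 0.020, 0.02, 0.5, 0.92)
  qs <- c(0.1, 1, 5, 20)
  expect_equal(reflectance_saa_q(qs, p1) / p1$mu_s * p1$mu_s,
               reflectance_saa_q(qs * 5, p2), tolerance = 1e-8)
  expect_equal(reflectance_diffuse_q(qs, p1), reflectance_diffuse_q(qs * 5, p2),
               tolerance = 1e-12)
  expect_equal(reflectance_snake_q(qs, p1), reflectance_snake_q(qs * 5, p2),
               tolerance = 1e-6)
})

test_that("diffuse term matches an independent diffusion solution", {
  # finite-difference solution of the 1D diffusion equation with the
  # extrapolated boundary and the same point source
  p <- optical_properties(1, 0.02, 0.003, 0.02, 0.45, 0.9)
  sc <- derived_scales(p)
  bm <- boundary_model(p)
  fd_reflectance <- function(q) {
    D <- 1 / (3 * sc$mu_t_red)
    z0 <- 2 * sc$l_t
    n <- 8000; L <- 40 / sc$mu_t_red
    h <- (L + bm$z_e) / n
    z <- seq(-bm$z_e, L, length.out = n + 1)
    main <- rep(2 * D / h^2 + p$mu_a + D * q^2, n - 1)
    off <- rep(-D / h^2, n - 2)
    rhs <- numeric(n - 1)
    i0 <- which.min(abs(z[-c(1, n + 1)] - z0))
    rhs[i0] <- 1 / h
    A <- diag(main)
    A[cbind(1:(n - 2), 2:(n - 1))] <- off
    A[cbind(2:(n - 1), 1:(n - 2))] <- off
    phi <- solve(A, rhs)
    isurf <- which.min(abs(z[-c(1, n + 1)]))
    D * (phi[isurf + 1] - phi[isurf - 1]) / (2 * h)
  }
  for (q in c(0, 0.05, 0.2)) {
    albedo <- sc$mu_s_red / sc$mu_t_red
    expect_equal(reflectance_diffuse_q(q, p), albedo * fd_reflectance(q),
                 tolerance = 1e-2)
  }
})

test_that("snake reflectance decreases with absorption", {
  qs <- c(0.05, 0.3, 1, 4)
  base <- reflectance_snake_q(qs, optical_properties(1, 0, 0.003, 0.02, 0.45, 0.92))
  for (mua in c(0.005, 0.02, 0.05)) {
    v <- reflectance_snake_q(qs, optical_properties(1, mua, 0.003, 0.02, 0.45, 0.92))
    expect_true(all(v <= base + 1e-12))
    base <- v
  }
})

test_that("piecewise total is continuous at the located crossover", {
  p <- toy_props()
  cr <- crossover_q(p)
  expect_true(cr$bracketed)
  low <- reflectance_snake_q(cr$q_c, p) + reflectance_diffuse_q(cr$q_c, p) +
    ballistic_plateau(p)
  high <- reflectance_saa_q(cr$q_c, p)
  expect_lt(abs(log(low / high)), 1e-4)
  prof <- reflectance_total_q(c(cr$q_c * 0.9, cr$q_c * 1.1), p, split = "piecewise")
  expect_identical(prof$branch, c("low", "high"))
})

test_that("real-space high-q form matches an accelerated Hankel oracle", {
  p <- toy_props()
  rr <- reflectance_saa_rho_highq(c(0.05, 0.2, 1), p)
  expect_equal(rr$delta_weight, ballistic_plateau(p))
  plateau <- ballistic_plateau(p)
  oracle <- vapply(rr$rho, function(rho) {
    zeros <- reflphase:::besselJ_zeros(300) / rho
    s <- numeric(300); lo <- 1e-9
    for (k in seq_along(s)) {
      s[k] <- stats::integrate(function(q)
        (reflectance_saa_highq(q, p) - plateau) * besselJ(q * rho, 0) * q,
        lo, zeros[k], rel.tol = 1e-10, subdivisions = 200L)$value
      lo <- zeros[k]
    }
    ps <- cumsum(s)
    x <- utils::tail(ps, 40)
    while (length(x) > 1) x <- (x[-1] + x[-length(x)]) / 2
    x / (2 * pi)
  }, numeric(1))
  expect_equal(rr$value, oracle, tolerance = 1e-3)
  # monotone decay well beyond the spreading length
  lT <- p$Theta / p$mu_s
  far <- reflectance_saa_rho_highq(lT * c(5, 10, 20, 40), p)$value
  expect_true(all(diff(far) < 0))
})
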