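# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# the polystyrene-in-water test suspensions (d in um, lambda 0.515 um)
case_props <- function(name = c("d150", "d150abs", "d049")) {
  name <- match.arg(name)
  cached(paste0("props_", name), function() {
    susp <- switch(name,
      d150 = sphere_suspension(1.50, 0.515),
      d150abs = tune_absorption(sphere_suspension(1.50, 0.515), 0.0130),
      d049 = sphere_suspension(0.49, 0.515))
    mie_bulk_properties(susp)
  })
}

# a small analytic medium for forward-model tests (no Mie machinery)
toy_props <- function(mu_a = 0.005) {
  optical_properties(mu_s = 1, mu_a = mu_a, mu_b = 0.0035,
                     p_b = 0.0175, Theta = 0.451, g = 0.92)
}

# Monte Carlo runs shared between tests (2e5 photons keeps each under ~6 s)
case_mc <- function(name, n_photons = 2e5, seed = 42) {
  key <- sprintf("mc_%s_%g_%d", name, n_photons, seed)
  cached(key, function() {
    run_mc(mc_config(case_props(name), n_photons = n_photons, seed = seed))
  })
}

# merit window used throughout: 0 < q <= 2 pi mu_t
merit_sel <- function(q, props) {
  mu_t <- props$mu_s + props$mu_a
  q > 0 & q <= 2 * pi * mu_t
}

# independent simple Monte Carlo for an isotropically scattering half space
# (analog absorption, direct cos(theta) sampling): oracle for run_mc
iso_albedo_oracle <- function(albedo, n = 4e4, seed = 1) {
  set.seed(seed)
  reflected <- 0
  for (i in seq_len(n)) {
    z <- 0; uz <- 1
    repeat {
      s <- stats::rexp(1)
      z <- z + uz * s
      if (z < 0) { reflected <- reflected + 1; break }
      if (stats::runif(1) > albedo) break       # absorbed
      uz <- stats::runif(1, -1, 1)              # isotropic
    }
  }
  reflected / n
}
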