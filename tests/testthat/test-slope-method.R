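tab <- nir_extinction_table()

test_that("slopes of exactly linear inputs are recovered with r^2 = 1", {
  rho <- c(2, 2.5, 3, 3.5)
  m <- data.frame(rho_cm = rho, phase_rad = 0.3 * rho,
                  ac = exp(1 - 1.2 * rho) / rho^2, wavelength_nm = 830)
  sp <- fit_slopes(m)
  expect_equal(sp$s_phase, 0.3, tolerance = 1e-12)
  expect_equal(sp$s_ac, -1.2, tolerance = 1e-12)
  expect_equal(sp$r2_ac, 1, tolerance = 1e-9)
  expect_equal(sp$r2_phase, 1, tolerance = 1e-9)
  # two points reduce to finite differences
  m2 <- m[1:2, ]
  m2$phase_rad <- c(0.5, 0.9)
  m2$ac <- c(3, 1) / m2$rho_cm^2
  sp2 <- fit_slopes(m2)
  expect_equal(sp2$s_phase, (0.9 - 0.5) / 0.5, tolerance = 1e-12)
  expect_equal(sp2$s_ac, (log(1) - log(3)) / 0.5, tolerance = 1e-12)
})

test_that("slope fitting validates its inputs", {
  m <- data.frame(rho_cm = c(2, 2), phase_rad = c(1, 1), ac = c(1, 1))
  expect_error(fit_slopes(m), "2 distinct separations")
  m2 <- data.frame(rho_cm = c(2, 3), phase_rad = c(1, 2), ac = c(1, -1))
  expect_error(fit_slopes(m2), "AC amplitudes")
  m3 <- data.frame(rho_cm = c(2, 3), phase_rad = c(1, NaN), ac = c(1, 1))
  expect_error(fit_slopes(m3), "non-finite")
})

test_that("surrogate-forward slopes recover the wavevector", {
  # amplitude slope equals -k_real exactly by construction of the model;
  # phase slope carries the small arctan curvature bias (< 3% for
  # cohort-typical optics)
  mua <- 0.2; musp <- 10.7
  k <- wavevector(mua, musp, fd_context(2))
  rho <- c(2, 2.5, 3, 3.5)
  m <- do.call(rbind, lapply(rho, function(r) {
    ctx <- fd_context(r)
    data.frame(rho_cm = r, phase_rad = flux_phase(mua, musp, ctx),
               ac = model_amplitude(mua, musp, ctx))
  }))
  sp <- fit_slopes(m)
  expect_equal(sp$s_ac, -k$k_real, tolerance = 1e-12)
  expect_lt(abs(sp$s_phase - k$k_imag) / k$k_imag, 0.03)
  # independent regression oracle for the phase slope
  ols <- cov(m$rho_cm, m$phase_rad) / var(m$rho_cm)
  expect_equal(sp$s_phase, ols, tolerance = 1e-12)
})

test_that("slope-to-optics inverts the wavevector relations", {
  k <- wavevector(0.1, 10, fd_context(2))
  op <- slopes_to_optics(list(s_ac = -k$k_real, s_phase = k$k_imag))
  expect_equal(op$mu_a, 0.1, tolerance = 1e-9)
  expect_equal(op$mu_s_prime, 10, tolerance = 1e-9)
  # frozen closed-form oracle for an arbitrary valid slope pair
  op2 <- slopes_to_optics(list(s_ac = -2.1, s_phase = 0.24))
  expect_equal(op2$mu_a, oracle$slope_mua, tolerance = 1e-12)
  expect_equal(op2$mu_s_prime, oracle$slope_musp, tolerance = 1e-12)
  # symmetric degenerate limit: s_phase -> -s_ac drives mu_a -> 0
  op3 <- slopes_to_optics(list(s_ac = -1, s_phase = 1 - 1e-9))
  expect_lt(op3$mu_a, 1e-8)
  expect_error(slopes_to_optics(list(s_ac = -1, s_phase = 1.1)),
               "nonphysical")
  expect_error(slopes_to_optics(list(s_ac = 1, s_phase = 0.2)), "physical")
})

test_that("recovered mu_a increases with true mu_a at fixed scattering", {
  rec <- vapply(c(0.1, 0.15, 0.2, 0.3), function(mua) {
    rho <- c(2, 2.5, 3, 3.5)
    m <- do.call(rbind, lapply(rho, function(r) {
      ctx <- fd_context(r)
      data.frame(rho_cm = r, phase_rad = flux_phase(mua, 10, ctx),
                 ac = model_amplitude(mua, 10, ctx))
    }))
    slopes_to_optics(fit_slopes(m))$mu_a
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("slope pipeline recovers optics and concentrations end to end", {
  for (set in c("two", "eight")) {
    wl <- fd_wavelengths(set)
    cs <- chromophore_set(60, 25, if (set == "eight") 8.5 else 0, 0.75)
    sl <- scatter_law(24.2, 1.611)
    sample <- list(list(
      id = 1, chromophores = cs, scatter = sl,
      optics = optical_properties(wl, absorption_spectrum(cs, tab, wl),
                                  scattering_spectrum(sl, wl))))
    meas <- forward_cohort_surrogate(sample, c(2, 2.5, 3, 3.5),
                                     phase_noise_sd = 0)
    out <- slope_pipeline(meas, tab, 0.75, wl)
    rel <- abs(out$optics$mu_a_est - sample[[1]]$optics$mu_a) /
      sample[[1]]$optics$mu_a
    expect_lt(max(rel), 0.02)    # near-linearity of the phase over 2-3.5 cm
    if (set == "two") {
      # exact-square two-chromophore branch: no CCO estimate
      expect_equal(out$concentrations$cco_est, 0)
    }
  }
})

test_that("slope pipeline reports missing wavelengths explicitly", {
  wl <- fd_wavelengths("two")
  cs <- chromophore_set(60, 25, 0, 0.75)
  sl <- scatter_law(24.2, 1.611)
  sample <- list(list(
    id = 1, chromophores = cs, scatter = sl,
    optics = optical_properties(wl, absorption_spectrum(cs, tab, wl),
                                scattering_spectrum(sl, wl))))
  meas <- forward_cohort_surrogate(sample, c(2, 2.5, 3, 3.5),
                                   phase_noise_sd = 0)
  meas <- meas[meas$wavelength_nm != 830, ]
  expect_error(slope_pipeline(meas, tab, 0.75, wl), "830")
})
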