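# Monte Carlo tests use modest photon budgets: enough for the statistical
# assertions while keeping the suite fast. The closer MC-vs-diffusion
# comparison (2e5 photons) lives in the acceptance suite.

geom <- mc_geometry()
v_med <- 29.9792458e9 / geom$n_medium

test_that("an empty photon budget gives all-zero TPSFs", {
  tp <- simulate_tpsf(0.1, 10, geom, n_photons = 0)
  expect_true(all(vapply(tp, function(x) all(x$weights == 0), logical(1))))
  expect_equal(length(tp[[1]]$weights), 1000)   # 10 ns / 10 ps
})

test_that("absorption weighting equals the mu_a = 0 run times exp(-mua*v*t)", {
  tp0 <- simulate_tpsf(0, 10, geom, n_photons = 3e4, seed = 7)
  tpa <- simulate_tpsf(0.15, 10, geom, n_photons = 3e4, seed = 7)
  for (d in seq_along(tp0)) {
    expect_identical(tpa[[d]]$weights,
                     tp0[[d]]$weights * exp(-0.15 * v_med * tp0[[d]]$times))
  }
})

test_that("TPSFs are causal and reproducible, and weights are conserved", {
  tp <- simulate_tpsf(0.1, 10, geom, n_photons = 3e4, seed = 11)
  for (x in tp) {
    ballistic <- x$detector_radius * geom$n_medium / 29.9792458 * 1e-9
    expect_equal(sum(x$weights[x$times < ballistic]), 0)
  }
  # determinism under a fixed seed
  tp2 <- simulate_tpsf(0.1, 10, geom, n_photons = 3e4, seed = 11)
  expect_identical(lapply(tp, `[[`, "weights"), lapply(tp2, `[[`, "weights"))
  # weight ledger closes exactly when absorption weighting is off
  tp0 <- simulate_tpsf(0, 10, geom, n_photons = 3e4, seed = 11)
  acc <- attr(tp0[[1]], "accounting")
  expect_identical(acc$w_top + acc$w_side + acc$w_expired, 3e4)
})

test_that("FD extraction reproduces single-impulse and two-bin analytics", {
  # impulse of weight w at t0 = 1 ns (bin 100 has centre 0.995 ns)
  tp <- tpsf_at_bins(101, 2.5)     # centre (101 - 0.5) * 10 ps = 1.005 ns
  t0 <- tp$times[101]
  fd <- fd_from_tpsf(tp, f_mod = 110e6)
  expect_equal(fd$dc, 2.5 * 10e-12)
  expect_equal(fd$ac, 2.5 * 10e-12, tolerance = 1e-12)
  expect_equal(fd$phase_rad, 2 * pi * 110e6 * t0, tolerance = 1e-12)
  # the 1 ns analytic value, using a tpsf whose bin centre is exactly 1 ns
  tp1 <- make_tpsf(1, bin_width = 2e-10)   # first bin centre 0.1 ns
  tp1$weights[] <- 0; tp1$weights[5] <- 1  # centre (5 - .5)*0.2 ns = 0.9...
  tp1$times <- tp1$times + 1e-10           # shift so bin 5 centres at 1 ns
  fd1 <- fd_from_tpsf(tp1, f_mod = 110e6)
  expect_equal(fd1$phase_rad, oracle$impulse_phase_1ns, tolerance = 1e-12)
  # impulse in the first bin centre ~ 5 ps: phase ~ 2*pi*f*5ps, near zero
  fd0 <- fd_from_tpsf(tpsf_at_bins(1, 1), f_mod = 110e6)
  expect_equal(fd0$phase_rad, 2 * pi * 110e6 * 5e-12, tolerance = 1e-12)
  # two-bin complex-arithmetic oracle: w = (.7, .3) at t = (.5, 1.2) ns
  tp2 <- tpsf_at_bins(c(51, 121), c(0.7, 0.3))
  expect_equal(tp2$times[51], 0.505e-9)
  tp2$times <- tp2$times - 0.005e-9        # centre the bins at .5 / 1.2 ns
  fd2 <- fd_from_tpsf(tp2, f_mod = 110e6)
  expect_equal(fd2$dc, oracle$twobin_dc, tolerance = 1e-14)
  expect_equal(fd2$ac, oracle$twobin_ac, tolerance = 1e-12)
  expect_equal(fd2$phase_rad, oracle$twobin_phase, tolerance = 1e-12)
  # an all-zero TPSF has no phase
  expect_error(fd_from_tpsf(make_tpsf(0)), "undefined|zero")
})

test_that("detected AC standard error scales as 1/sqrt(n_photons)", {
  # a single close detector collects enough events for stable SE estimates
  g1 <- mc_geometry(detector_radii = 1.0)
  ac_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      tp <- simulate_tpsf(0.1, 10, g1, n_photons = n, seed = s)
      fd_from_tpsf(tp[[1]])$ac / n          # per-photon amplitude
    }, numeric(1))
  }
  se1 <- sd(ac_at(5e3, 101:116))
  se4 <- sd(ac_at(2e4, 201:216))
  # quadrupling the photon budget should halve the AC standard error
  expect_gt(se1 / se4, 2 * 0.7)
  expect_lt(se1 / se4, 2 * 1.3)
})

test_that("mean time of flight agrees with the diffusion-theory oracle", {
  tp <- simulate_tpsf(0.1, 10, geom, n_photons = 1e5, seed = 42)
  x <- tp[[1]]                                   # rho = 2.0 cm
  mc_mean <- sum(x$weights * x$times) / sum(x$weights)
  # oracle: first moment of the semi-infinite diffusion TPSF
  # R(t) ~ t^(-5/2) exp(-mua v t) exp(-(rho^2 + z0^2)/(4 D v t))
  D <- 1 / (3 * 10.1); z0 <- 1 / 10
  t <- seq(1e-12, 10e-9, length.out = 20000)
  R <- t^(-2.5) * exp(-0.1 * v_med * t) *
    exp(-(2^2 + z0^2) / (4 * D * v_med * t))
  oracle_mean <- sum(R * t) / sum(R)
  expect_equal(mc_mean, oracle_mean, tolerance = 0.15)
})

test_that("cohort MC forward has the right cardinality and determinism", {
  cfg <- cohort_config(n_samples = 1, wavelength_set = "two", seed = 3)
  samples <- generate_cohort(cfg)
  expect_warning(
    m <- forward_cohort_mc(samples, geom, fd_wavelengths("two"),
                           n_photons = 2e4, seed = 5),
    "photon budget")
  expect_equal(nrow(m), 1 * 2 * 4)   # samples x wavelengths x radii
  expect_true(all(m$dc >= m$ac), info = "dc >= ac")
  expect_true(all(m$phase_rad >= 0 & m$phase_rad < 2 * pi))
  m2 <- suppressWarnings(
    forward_cohort_mc(samples, geom, fd_wavelengths("two"),
                      n_photons = 2e4, seed = 5))
  expect_identical(m, m2)
})

test_that("TPSF text round trip preserves data and metadata", {
  tp <- simulate_tpsf(0.12, 11, geom, n_photons = 1e4, seed = 9,
                      wavelength = 830)[[2]]
  path <- tempfile(fileext = ".tpsf")
  write_tpsf(tp, path)
  back <- read_tpsf(path)
  expect_equal(back$weights, tp$weights, tolerance = 1e-9)
  expect_equal(back$detector_radius, tp$detector_radius)
  expect_equal(back$mu_a, tp$mu_a)
  expect_equal(back$n_photons, tp$n_photons)
  unlink(path)
})

test_that("geometry validation rejects unphysical configurations", {
  expect_error(mc_geometry(g = 1), "anisotropy")
  expect_error(mc_geometry(detector_radii = c(2, 4.99)), "fit inside")
  expect_error(mc_geometry(detector_radii = c(2, 2.05)), "overlap")
})
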