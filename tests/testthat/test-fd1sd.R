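wl8 <- fd_wavelengths("eight")
wl2 <- fd_wavelengths("two")

test_that("edge barrier is zero at midpoints and alpha at the bounds", {
  b <- fd1sd_bounds("eight", alpha = 1)
  expect_equal(edge_barrier(b$centre, b), 0)
  # one parameter at its upper bound, others at midpoints
  th <- b$centre
  th["a"] <- b$upper["a"]
  expect_equal(edge_barrier(th, b), 1)
  # printed bounds: HbO in (30, 90) gives c = 60, h = 30; HbO = 75 with
  # alpha = 2 contributes 2 * 0.5^2 = 0.5
  b2 <- fd1sd_bounds("eight", alpha = c(2, 0, 0, 0, 0))
  th2 <- b2$centre
  expect_equal(b2$centre[["hbo"]], 60)
  expect_equal(b2$half_width[["hbo"]], 30)
  th2["hbo"] <- 75
  expect_equal(edge_barrier(th2, b2), 0.5)
})

test_that("phase-residual cost is the sum of squares plus the barrier", {
  cfg <- fd1sd_config()
  b0 <- fd1sd_bounds("eight", alpha = 0)
  ph_true <- model_phases(rep_theta, wl8, 2)
  # inverse crime at the truth with no barrier: exactly zero
  expect_equal(as.numeric(
    phase_residual_cost(rep_theta, ph_true, wl8, 2, b0, cfg)), 0)
  # hand-set residuals on two wavelengths: (0.01)^2 + (0.02)^2 = 5e-4
  b0_2 <- fd1sd_bounds("two", alpha = 0)
  th2 <- rep_theta[c("hbo", "hb", "a", "b")]
  ph2 <- phase_model(th2, wl2, 2, cfg, "two")$phase
  cost <- phase_residual_cost(th2, ph2 + c(0.01, -0.02), wl2, 2, b0_2, cfg)
  expect_equal(as.numeric(cost), 5e-4, tolerance = 1e-12)
  expect_equal(attr(cost, "reg_term"), 0)
  # degenerate zero measurements at the midpoint: cost is sum of phi^2
  mid <- fd1sd_bounds("eight")$centre
  ph_mid <- model_phases(mid, wl8, 2)
  expect_equal(as.numeric(
    phase_residual_cost(mid, rep(0, 8), wl8, 2, b0, cfg)),
    sum(ph_mid^2), tolerance = 1e-12)
  expect_error(
    phase_residual_cost(mid, rep(0, 3), wl8, 2, b0, cfg), "per wavelength")
})

test_that("analytic gradient of the cost matches finite differences", {
  cfg <- fd1sd_config()
  set.seed(9)
  for (i in 1:5) {
    th <- c(hbo = runif(1, 35, 85), hb = runif(1, 8, 35),
            cco_redox = runif(1, 1, 15), a = runif(1, 16, 45),
            b = runif(1, 0.6, 1.9))
    m <- phase_model(th, wl8, 2, cfg, "eight", jacobian = TRUE)
    fd <- vapply(seq_along(th), function(j) {
      h <- abs(th[j]) * 1e-6
      tp <- th; tm <- th
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      (phase_model(tp, wl8, 2, cfg, "eight")$phase -
         phase_model(tm, wl8, 2, cfg, "eight")$phase) / (2 * h)
    }, numeric(8))
    expect_equal(unname(m$jacobian), unname(fd), tolerance = 1e-5)
  }
})

test_that("noiseless eight-wavelength inverse crime is recovered", {
  cfg <- fd1sd_config()
  truth <- c(hbo = 63, hb = 24, cco_redox = 9.1, a = 24, b = 1.62)
  ph <- model_phases(truth, wl8, 2)
  fit <- fit_fd1sd(ph, wl8, 2, "eight", cfg)
  rel <- abs(fit$theta[c("hbo", "hb", "cco_redox")] -
               truth[c("hbo", "hb", "cco_redox")]) /
    truth[c("hbo", "hb", "cco_redox")]
  expect_lt(max(rel), 0.01)
  expect_true(fit$converged)
  expect_equal(fit$final_cost, fit$data_term + fit$reg_term,
               tolerance = 1e-12)
  # with no barrier at all the system is perfectly fittable
  cfg0 <- fd1sd_config(alpha = 0)
  fit0 <- fit_fd1sd(ph, wl8, 2, "eight", cfg0)
  expect_lt(fit0$data_term, 1e-12)
})

test_that("different fixed initializations agree on noiseless data", {
  truth <- c(hbo = 63, hb = 24, cco_redox = 9.1, a = 24, b = 1.62)
  ph <- model_phases(truth, wl8, 2)
  fit_mid <- fit_fd1sd(ph, wl8, 2, "eight", fd1sd_config())
  fit_off <- fit_fd1sd(ph, wl8, 2, "eight",
                       fd1sd_config(init = truth * 1.2))
  expect_equal(fit_off$theta, fit_mid$theta, tolerance = 5e-3)
})

test_that("two-wavelength mode fits four parameters without CCO", {
  th2 <- c(hbo = 58, hb = 27, a = 24.2, b = 1.611)
  cfg <- fd1sd_config()
  ph <- phase_model(th2, wl2, 2, cfg, "two")$phase
  fit <- fit_fd1sd(ph, wl2, 2, "two", cfg)
  expect_named(fit$theta, c("hbo", "hb", "a", "b"))
  expect_false("cco_redox" %in% names(fit$theta))
  expect_equal(fit$mode, "two")
  # the two phases are fitted essentially exactly (under-determined system)
  expect_lt(fit$data_term, 1e-14)
})

test_that("estimates respect the bounds exactly, objective never increases", {
  cfg <- fd1sd_config()
  b <- fd1sd_bounds("eight")
  # truth outside the admissible box: the fit must clamp within bounds
  out_truth <- c(hbo = 95, hb = 45, cco_redox = 9, a = 24.2, b = 1.611)
  ph <- model_phases(out_truth, wl8, 2)
  fit <- fit_fd1sd(ph, wl8, 2, "eight", cfg)
  expect_true(all(fit$theta >= b$lower & fit$theta <= b$upper))
  # objective decrease relative to the midpoint initialization
  mid_cost <- phase_residual_cost(b$centre, ph, wl8, 2,
                                  fd1sd_bounds("eight", cfg$alpha), cfg)
  expect_lte(fit$final_cost, as.numeric(mid_cost))
})

test_that("out-of-range phases are wrapped with a warning", {
  truth <- c(hbo = 63, hb = 24, cco_redox = 9.1, a = 24, b = 1.62)
  ph <- model_phases(truth, wl8, 2)
  expect_warning(fit <- fit_fd1sd(ph + 2 * pi, wl8, 2, "eight"),
                 "wrapped")
  rel <- abs(fit$theta[["hbo"]] - 63) / 63
  expect_lt(rel, 0.01)
  expect_error(fit_fd1sd(c(ph[-1], NA), wl8, 2, "eight"), "finite")
})

test_that("derived optics delegate to the spectral closed forms", {
  cfg <- fd1sd_config()
  tab <- cfg$table
  op <- derived_optics(rep_theta, wl8, cfg)
  cs <- chromophore_set(60, 25, 8.5, 0.75)
  expect_equal(op$mu_a, absorption_spectrum(cs, tab, wl8))
  expect_equal(op$mu_s_prime,
               scattering_spectrum(scatter_law(24.2, 1.611), wl8))
  # a fit object is accepted directly
  ph <- model_phases(rep_theta, wl8, 2)
  fit <- fit_fd1sd(ph, wl8, 2, "eight", cfg)
  op2 <- derived_optics(fit, wl8, cfg)
  expect_equal(op2$mu_a, absorption_spectrum(cs, tab, wl8),
               tolerance = 0.02)
})
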