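# Frozen oracle values, computed independently of the package:
# closed forms evaluated with 40-digit arbitrary-precision arithmetic
# (mpmath), and hand/dot-product computations on the shipped fixture.

oracle <- list(
  # mu_s'(800) = 24.2 * (800/500)^(-1.611)
  musp_800 = 11.34953514212573,
  # wavevector at mu_a = 0.1, mu_s' = 10, f = 110 MHz, n = 1.37
  k_real = 1.761752005963934,
  k_imag = 0.2716065730389157,
  # flux phase, same optics, rho = 2 cm
  phase_rho2 = 0.4236986477761921,
  # AC amplitude exp(-k_real * rho)/rho^2 at rho = 2.5 cm
  amp_rho2.5 = 1.955789210718155e-3,
  # dot product over the 830 nm fixture row:
  # (HbO, Hb, CCO) = (60, 25, 8.5) uM, water fraction 0.75
  mua_830 = 0.23753268,
  # FD of a two-bin signal: w = (0.7, 0.3) at t = (0.5, 1.2) ns,
  # dt = 10 ps, f = 110 MHz
  twobin_dc = 1e-11,
  twobin_ac = 9.756009177730570e-12,
  twobin_phase = 0.4891027183298933,
  # phase of a single impulse at t0 = 1 ns: 2*pi*f*t0
  impulse_phase_1ns = 0.6911503837897545,
  # slope relations at s_ac = -2.1, s_phase = 0.24, f = 110 MHz, n = 1.37
  slope_mua = 0.1363768601332197,
  slope_musp = 10.50179151082639
)

# representative tissue parameters used across tests
rep_theta <- c(hbo = 60, hb = 25, cco_redox = 8.5, a = 24.2, b = 1.611)

# forward phases for a parameter vector (thin wrapper used by many tests)
model_phases <- function(theta, wavelengths, rho, mode = "eight",
                         config = fd1sd_config()) {
  phase_model(theta, wavelengths, rho, config, mode)$phase
}

# build a tpsf object by hand (for the FD-extractor unit tests)
make_tpsf <- function(weights, bin_width = 10e-12, window = 10e-9,
                      rho = 2) {
  n_bins <- round(window / bin_width)
  w <- numeric(n_bins)
  w[seq_along(weights)] <- weights
  structure(list(bin_width = bin_width, window = window,
                 times = (seq_len(n_bins) - 0.5) * bin_width, weights = w,
                 detector_radius = rho, wavelength = NA_real_,
                 n_photons = NA_integer_, seed = NA_integer_,
                 mu_a = 0, mu_s_prime = 10),
            class = "tpsf")
}

# place weights at given bin indices
tpsf_at_bins <- function(bins, weights, ...) {
  tp <- make_tpsf(0, ...)
  tp$weights[bins] <- weights
  tp
}
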