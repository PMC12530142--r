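# Conventional multidistance slope method: linear fits of phase and
# ln(rho^2 * AC) against source-detector separation, slope-to-optics
# conversion via the infinite-medium FD diffusion relations, then
# Beer-Lambert unmixing. Units: slopes cm^-1 (AC) and rad/cm (phase).

#' Fit multidistance slopes at one wavelength
#'
#' Ordinary least-squares fits of `phase_rad ~ rho_cm` and
#' `log(rho_cm^2 * ac) ~ rho_cm` across the available source-detector
#' separations. In a diffusive medium the AC slope is negative (attenuation)
#' and the phase slope positive (increasing lag).
#'
#' @param measurements FD measurement rows at a single wavelength: a data
#'   frame with columns `rho_cm`, `ac`, `phase_rad` (and optionally
#'   `wavelength_nm`).
#' @return Object of class `slope_pair`: list with `s_ac`, `s_phase`,
#'   `r2_ac`, `r2_phase`, `wavelength`.
#' @export
#' @examples
#' m <- data.frame(rho_cm = c(2, 2.5, 3, 3.5),
#'                 ac = exp(1 - 1.2 * c(2, 2.5, 3, 3.5)) / c(2, 2.5, 3, 3.5)^2,
#'                 phase_rad = 0.3 * c(2, 2.5, 3, 3.5))
#' fit_slopes(m)
fit_slopes <- function(measurements) {
  need <- c("rho_cm", "ac", "phase_rad")
  if (!all(need %in% names(measurements))) {
    stop("measurements need columns: ", paste(need, collapse = ", "))
  }
  if ("wavelength_nm" %in% names(measurements) &&
      length(unique(measurements$wavelength_nm)) > 1) {
    stop("fit_slopes expects measurements at a single wavelength")
  }
  if (length(unique(measurements$rho_cm)) < 2) {
    stop("need measurements at >= 2 distinct separations to fit slopes")
  }
  if (any(!is.finite(measurements$phase_rad)) ||
      any(!is.finite(measurements$ac))) {
    stop("non-finite phase or AC values")
  }
  if (any(measurements$ac <= 0)) {
    stop("AC amplitudes must be > 0 to take logarithms")
  }
  rho <- measurements$rho_cm
  fit_ph <- lm(y ~ rho, data = data.frame(y = measurements$phase_rad,
                                          rho = rho))
  fit_ac <- lm(y ~ rho, data = data.frame(
    y = log(rho^2 * measurements$ac), rho = rho))
  r2 <- function(f) {
    tss <- sum((f$model$y - mean(f$model$y))^2)
    if (tss == 0) return(1)
    max(0, 1 - sum(f$residuals^2) / tss)
  }
  structure(
    list(s_ac = unname(coef(fit_ac)[2]), s_phase = unname(coef(fit_ph)[2]),
         r2_ac = r2(fit_ac), r2_phase = r2(fit_ph),
         wavelength = if ("wavelength_nm" %in% names(measurements)) {
           measurements$wavelength_nm[1]
         } else NA_real_),
    class = "slope_pair")
}

#' Optical properties from multidistance slopes
#'
#' Converts the AC and phase slopes into absolute optical properties using
#' the infinite-medium frequency-domain diffusion relations. With
#' `k_r = -s_ac` and `k_i = s_phase`:
#' \deqn{\mu_a = \frac{\omega}{2v}\left(\frac{k_r}{k_i} -
#'   \frac{k_i}{k_r}\right), \quad D = \frac{\omega}{2 v k_r k_i}, \quad
#'   \mu_s' = \frac{1}{3D} - \mu_a,}
#' the exact inverse of the [wavevector()] definitions.
#'
#' @param sp A `slope_pair` from [fit_slopes()], or any list with `s_ac` and
#'   `s_phase`.
#' @param f_mod Modulation frequency (Hz).
#' @param n_medium Refractive index of the medium.
#' @return List with `mu_a` and `mu_s_prime` (cm^-1).
#' @export
#' @examples
#' k <- wavevector(0.1, 10, fd_context(rho = 2))
#' slopes_to_optics(list(s_ac = -k$k_real, s_phase = k$k_imag))
slopes_to_optics <- function(sp, f_mod = 110e6, n_medium = 1.37) {
  if (sp$s_ac >= 0 || sp$s_phase <= 0) {
    stop("physical media require s_ac < 0 and s_phase > 0")
  }
  k_r <- -sp$s_ac
  k_i <- sp$s_phase
  if (k_i >= k_r) {
    stop("nonphysical slopes: |s_phase| >= |s_ac| implies mu_a <= 0")
  }
  omega <- 2 * pi * f_mod
  v <- .c0_cm_ns / n_medium * 1e9
  mu_a <- (omega / (2 * v)) * (k_r / k_i - k_i / k_r)
  D <- omega / (2 * v * k_r * k_i)
  list(mu_a = mu_a, mu_s_prime = 1 / (3 * D) - mu_a)
}

#' Multidistance slope pipeline: measurements to concentrations
#'
#' For every sample and wavelength in an FD measurement table, fits the
#' multidistance slopes, converts them to absolute optical properties, and
#' finally unmixes chromophore concentrations from the per-wavelength
#' absorption spectrum (exactly-determined with two wavelengths and two
#' haemoglobin species, least squares with more).
#'
#' @param measurements FD measurement table with columns `sample_id`,
#'   `wavelength_nm`, `rho_cm`, `f_mod_hz`, `ac`, `phase_rad`.
#' @param table An [nir_extinction_table()].
#' @param water_fraction Fixed water volume fraction used in unmixing.
#' @param wavelengths Wavelength set that must be present for every sample;
#'   defaults to all wavelengths in `measurements`.
#' @return List with two data frames: `optics` (`sample_id`,
#'   `wavelength_nm`, `mu_a_est`, `mu_sp_est`) and `concentrations`
#'   (`sample_id`, `hbo_est`, `hb_est`, `cco_est`).
#' @export
slope_pipeline <- function(measurements, table = nir_extinction_table(),
                           water_fraction = 0.75, wavelengths = NULL) {
  if (is.null(wavelengths)) {
    wavelengths <- sort(unique(measurements$wavelength_nm))
  }
  optics_rows <- list()
  conc_rows <- list()
  for (sid in unique(measurements$sample_id)) {
    ms <- measurements[measurements$sample_id == sid, ]
    missing_wl <- setdiff(wavelengths, unique(ms$wavelength_nm))
    if (length(missing_wl)) {
      stop("sample ", sid, " lacks measurements at wavelength(s): ",
           paste(missing_wl, collapse = ", "))
    }
    est <- vapply(wavelengths, function(wl) {
      mw <- ms[ms$wavelength_nm == wl, ]
      op <- slopes_to_optics(fit_slopes(mw), f_mod = mw$f_mod_hz[1])
      c(op$mu_a, op$mu_s_prime)
    }, numeric(2))
    optics_rows[[length(optics_rows) + 1L]] <- data.frame(
      sample_id = sid, wavelength_nm = wavelengths,
      mu_a_est = est[1, ], mu_sp_est = est[2, ])
    op <- optical_properties(wavelengths, est[1, ], est[2, ])
    cs <- unmix_concentrations(op, table, water_fraction)
    conc_rows[[length(conc_rows) + 1L]] <- data.frame(
      sample_id = sid, hbo_est = cs$hbo, hb_est = cs$hb,
      cco_est = cs$cco_redox)
  }
  list(optics = do.call(rbind, optics_rows),
       concentrations = do.call(rbind, conc_rows))
}
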