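# Synthetic cohort generation, surrogate forward data, MAE/MRE evaluation
# and the experiment runner comparing the multidistance slope method with
# the single-distance phase-only fit at each separation.
# Units: concentrations uM; a cm^-1; phase noise rad; lengths cm.

#' Cohort configuration
#'
#' Describes a population of synthetic tissue samples. Defaults encode the
#' standard simulated brain-tissue cohort: mean concentrations 60 (HbO),
#' 25 (Hb) and 8.5 uM (CCOredox, roughly 10% of total haemoglobin), each
#' perturbed with zero-mean Gaussian noise of SD 10% of the mean (truncated
#' at zero); water fraction fixed at 0.75; power-law scattering about
#' `a = 24.2`, `b = 1.611` (reference 500 nm), each perturbed by 1%.
#' With the two-wavelength (haemoglobin-only) set the cohort carries no
#' CCOredox: those samples are defined by HbO and Hb alone.
#'
#' @param n_samples Number of samples ("subjects").
#' @param mean_hbo,mean_hb,mean_cco Mean concentrations (uM).
#' @param concentration_cv Gaussian SD as a fraction of each mean.
#' @param water_fraction Fixed water volume fraction.
#' @param scatter_a,scatter_b,lambda0 Power-law scattering base parameters.
#' @param scatter_cv Gaussian SD as a fraction of `a` and `b`.
#' @param wavelength_set `"eight"` or `"two"` (see [fd_wavelengths()]).
#' @param seed Integer seed for cohort generation.
#' @return List of class `cohort_config`.
#' @export
#' @examples
#' cohort_config(seed = 1)
cohort_config <- function(n_samples = 30, mean_hbo = 60, mean_hb = 25,
                          mean_cco = 8.5, concentration_cv = 0.10,
                          water_fraction = 0.75, scatter_a = 24.2,
                          scatter_b = 1.611, lambda0 = 500,
                          scatter_cv = 0.01,
                          wavelength_set = c("eight", "two"), seed = 1) {
  wavelength_set <- match.arg(wavelength_set)
  stopifnot(n_samples >= 1, concentration_cv >= 0, scatter_cv >= 0)
  structure(list(n_samples = n_samples, mean_hbo = mean_hbo,
                 mean_hb = mean_hb, mean_cco = mean_cco,
                 concentration_cv = concentration_cv,
                 water_fraction = water_fraction, scatter_a = scatter_a,
                 scatter_b = scatter_b, lambda0 = lambda0,
                 scatter_cv = scatter_cv, wavelength_set = wavelength_set,
                 seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic tissue cohort
#'
#' Draws per-sample chromophore concentrations and scattering-law parameters
#' from the configured Gaussian perturbations (concentrations truncated at
#' zero), and attaches the derived per-wavelength optical properties.
#'
#' @param config A [cohort_config()].
#' @param table An [nir_extinction_table()].
#' @return List of tissue samples; each is a list with `id`,
#'   `chromophores` ([chromophore_set()]), `scatter` ([scatter_law()]) and
#'   `optics` ([optical_properties()] over the configured wavelength set).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 3, seed = 1))
#' cohort[[1]]$chromophores
generate_cohort <- function(config = cohort_config(),
                            table = nir_extinction_table()) {
  stopifnot(inherits(config, "cohort_config"))
  wl <- fd_wavelengths(config$wavelength_set)
  with_cco <- config$wavelength_set == "eight"
  set.seed(config$seed)
  n <- config$n_samples
  cv <- config$concentration_cv
  hbo <- pmax(rnorm(n, config$mean_hbo, cv * config$mean_hbo), 0)
  hb <- pmax(rnorm(n, config$mean_hb, cv * config$mean_hb), 0)
  cco <- if (with_cco) {
    pmax(rnorm(n, config$mean_cco, cv * config$mean_cco), 0)
  } else {
    rep(0, n)
  }
  a <- rnorm(n, config$scatter_a, config$scatter_cv * config$scatter_a)
  b <- rnorm(n, config$scatter_b, config$scatter_cv * config$scatter_b)
  lapply(seq_len(n), function(i) {
    cs <- chromophore_set(hbo[i], hb[i], cco[i], config$water_fraction)
    sl <- scatter_law(a[i], b[i], config$lambda0)
    list(id = i, chromophores = cs, scatter = sl,
         optics = optical_properties(
           wl, absorption_spectrum(cs, table, wl),
           scattering_spectrum(sl, wl)))
  })
}

# Long-format truth table for a cohort
cohort_truth <- function(samples) {
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$id, hbo = s$chromophores$hbo,
               hb = s$chromophores$hb, cco = s$chromophores$cco_redox,
               a = s$scatter$a, b = s$scatter$b)
  }))
}

#' Closed-form surrogate forward data for a cohort
#'
#' Generates FD measurements from the diffusion forward model instead of
#' Monte Carlo: phases from [flux_phase()] (plus optional additive Gaussian
#' phase noise) and AC/DC amplitudes from [model_amplitude()]. This is the
#' fast, noise-controlled stand-in for the Monte Carlo forward chain.
#'
#' @param samples Cohort from [generate_cohort()].
#' @param rhos Source-detector separations (cm).
#' @param f_mod Modulation frequency (Hz).
#' @param n_medium Refractive index.
#' @param phase_noise_sd SD of additive Gaussian phase noise (radians;
#'   0 for noiseless data).
#' @param seed Seed for the noise draws.
#' @return FD measurement table (`sample_id`, `wavelength_nm`, `rho_cm`,
#'   `f_mod_hz`, `dc`, `ac`, `phase_rad`).
#' @export
forward_cohort_surrogate <- function(samples, rhos = c(2, 2.5, 3, 3.5),
                                     f_mod = 110e6, n_medium = 1.37,
                                     phase_noise_sd = 0.0035, seed = 1) {
  set.seed(seed)
  rows <- lapply(samples, function(s) {
    op <- s$optics
    per_rho <- lapply(rhos, function(rho) {
      ctx <- fd_context(rho, f_mod, n_medium)
      data.frame(sample_id = s$id, wavelength_nm = op$wavelength_nm,
                 rho_cm = rho, f_mod_hz = f_mod,
                 dc = model_amplitude(op$mu_a, op$mu_s_prime, ctx, "dc"),
                 ac = model_amplitude(op$mu_a, op$mu_s_prime, ctx, "ac"),
                 phase_rad = flux_phase(op$mu_a, op$mu_s_prime, ctx))
    })
    do.call(rbind, per_rho)
  })
  out <- do.call(rbind, rows)
  if (phase_noise_sd > 0) {
    out$phase_rad <- out$phase_rad + rnorm(nrow(out), 0, phase_noise_sd)
  }
  out
}

#' MAE / MRE evaluation of estimates against truth
#'
#' Mean absolute error `MAE = mean(|est - truth|)` (physical units) and
#' mean relative error `MRE = mean(|est - truth| / truth) * 100` (%),
#' computed per parameter and per method.
#'
#' @param estimates Data frame with columns `sample_id`, `method`,
#'   `parameter`, `estimate`.
#' @param truth Data frame with columns `sample_id`, `parameter`, `truth`.
#' @return Data frame with columns `method`, `parameter`, `mae`, `mre`,
#'   `n`.
#' @export
#' @examples
#' est <- data.frame(sample_id = 1:3, method = "demo", parameter = "hbo",
#'                   estimate = c(63, 57, 60))
#' tru <- data.frame(sample_id = 1:3, parameter = "hbo", truth = 60)
#' evaluate_estimates(est, tru)
evaluate_estimates <- function(estimates, truth) {
  m <- merge(estimates, truth, by = c("sample_id", "parameter"))
  if (nrow(m) < nrow(estimates)) {
    miss <- !paste(estimates$sample_id, estimates$parameter) %in%
      paste(truth$sample_id, truth$parameter)
    stop("no ground truth for: ",
         paste(unique(paste(estimates$sample_id[miss],
                            estimates$parameter[miss])), collapse = "; "))
  }
  out <- do.call(rbind, lapply(
    split(m, list(m$method, m$parameter), drop = TRUE), function(g) {
      err <- abs(g$estimate - g$truth)
      data.frame(method = g$method[1], parameter = g$parameter[1],
                 mae = mean(err), mre = mean(err / g$truth) * 100,
                 n = nrow(g))
    }))
  rownames(out) <- NULL
  out[order(out$parameter, out$method), ]
}

#' Run the full method-comparison experiment
#'
#' Generates a cohort, produces forward FD data (closed-form surrogate or
#' Monte Carlo), runs the multidistance slope method on all separations and
#' the single-distance phase-only fit independently at each separation
#' (labelled `SD1`, `SD2`, ... in increasing rho), and evaluates MAE/MRE
#' against the generating truth.
#'
#' @param config A [cohort_config()].
#' @param forward `"surrogate"` (closed-form, default) or `"mc"`.
#' @param rhos Source-detector separations (cm).
#' @param phase_noise_sd Gaussian phase noise SD for the surrogate forward
#'   (radians).
#' @param n_photons Photon budget per (sample, wavelength) for the MC
#'   forward.
#' @param seed Seed for the forward noise / Monte Carlo (the cohort uses
#'   `config$seed`).
#' @param fit_config An [fd1sd_config()].
#' @param out_dir Optional directory: if given, writes `truth.csv`,
#'   `measurements.csv`, `slope_results.csv`, `fd1sd_results.csv`,
#'   `error_report.csv` and a `manifest` of key=value lines.
#' @return List with `truth`, `measurements`, `slope`, `fd1sd` (per-sample
#'   fit results), `errors` (the [evaluate_estimates()] report) and
#'   `manifest`.
#' @export
run_experiment <- function(config = cohort_config(),
                           forward = c("surrogate", "mc"),
                           rhos = c(2, 2.5, 3, 3.5),
                           phase_noise_sd = 0.0035, n_photons = 2e5,
                           seed = 1, fit_config = fd1sd_config(),
                           out_dir = NULL) {
  forward <- match.arg(forward)
  table <- fit_config$table
  mode <- config$wavelength_set
  wl <- fd_wavelengths(mode)
  samples <- generate_cohort(config, table)
  truth_wide <- cohort_truth(samples)
  meas <- if (forward == "surrogate") {
    forward_cohort_surrogate(samples, rhos, fit_config$f_mod,
                             fit_config$n_medium, phase_noise_sd, seed)
  } else {
    forward_cohort_mc(samples, mc_geometry(detector_radii = rhos),
                      wl, n_photons, fit_config$f_mod, seed)
  }
  sl <- slope_pipeline(meas, table, config$water_fraction, wl)
  sd_labels <- paste0("SD", seq_along(sort(rhos)))
  fits <- list()
  for (i in seq_along(rhos)) {
    rho <- sort(rhos)[i]
    for (sid in unique(meas$sample_id)) {
      mr <- meas[meas$sample_id == sid & meas$rho_cm == rho, ]
      mr <- mr[match(wl, mr$wavelength_nm), ]
      fit <- fit_fd1sd(mr$phase_rad, wl, rho, mode, fit_config)
      fits[[length(fits) + 1L]] <- data.frame(
        sample_id = sid, rho_cm = rho, method = sd_labels[i],
        mode = mode, hbo_est = fit$theta[["hbo"]],
        hb_est = fit$theta[["hb"]],
        cco_est = if (mode == "eight") fit$theta[["cco_redox"]] else NA,
        a_est = fit$theta[["a"]], b_est = fit$theta[["b"]],
        final_cost = fit$final_cost, converged = fit$converged)
    }
  }
  fd1sd_results <- do.call(rbind, fits)

  params <- c("hbo", "hb", if (mode == "eight") "cco")
  truth_long <- do.call(rbind, lapply(params, function(p) {
    data.frame(sample_id = truth_wide$sample_id, parameter = p,
               truth = truth_wide[[p]])
  }))
  est_long <- rbind(
    do.call(rbind, lapply(params, function(p) {
      data.frame(sample_id = sl$concentrations$sample_id, method = "SM",
                 parameter = p,
                 estimate = sl$concentrations[[paste0(p, "_est")]])
    })),
    do.call(rbind, lapply(params, function(p) {
      data.frame(sample_id = fd1sd_results$sample_id,
                 method = fd1sd_results$method, parameter = p,
                 estimate = fd1sd_results[[paste0(p, "_est")]])
    })))
  errors <- evaluate_estimates(est_long, truth_long)

  manifest <- c(
    sprintf("wavelength_set=%s", mode),
    sprintf("n_samples=%d", config$n_samples),
    sprintf("forward=%s", forward),
    sprintf("rhos=%s", paste(rhos, collapse = ",")),
    sprintf("phase_noise_sd=%g", phase_noise_sd),
    sprintf("n_photons=%g", n_photons),
    sprintf("cohort_seed=%d", config$seed),
    sprintf("forward_seed=%d", seed),
    sprintf("alpha=%s", paste(fit_config$alpha, collapse = ",")),
    sprintf("package_version=%s",
            as.character(utils::packageVersion("fdphase"))))
  out <- list(truth = truth_wide, measurements = meas, slope = sl,
              fd1sd = fd1sd_results, errors = errors, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(truth_wide, file.path(out_dir, "truth.csv"),
              row.names = FALSE)
    write.csv(meas, file.path(out_dir, "measurements.csv"),
              row.names = FALSE)
    write.csv(merge(sl$optics, sl$concentrations, by = "sample_id"),
              file.path(out_dir, "slope_results.csv"), row.names = FALSE)
    write.csv(fd1sd_results, file.path(out_dir, "fd1sd_results.csv"),
              row.names = FALSE)
    write.csv(errors, file.path(out_dir, "error_report.csv"),
              row.names = FALSE)
    writeLines(manifest, file.path(out_dir, "manifest"))
  }
  out
}

#' Write / read FD measurement tables
#'
#' CSV exchange format with columns `sample_id`, `wavelength_nm`, `rho_cm`,
#' `f_mod_hz`, `dc`, `ac`, `phase_rad`.
#'
#' @param measurements FD measurement data frame.
#' @param path File path.
#' @export
write_fd_measurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_measurements
#' @export
read_fd_measurements <- function(path) {
  d <- read.csv(path)
  need <- c("sample_id", "wavelength_nm", "rho_cm", "f_mod_hz", "dc", "ac",
            "phase_rad")
  if (!all(need %in% names(d))) {
    stop("FD measurement table must have columns: ",
         paste(need, collapse = ", "))
  }
  d
}
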