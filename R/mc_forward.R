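# Time-resolved Monte Carlo forward model and Fourier-domain extraction of
# frequency-domain quantities (DC, AC, phase) at the modulation frequency.
# Units: lengths cm; time s (bin width 10 ps, window 10 ns by default);
# mu_a, mu_s' cm^-1; phase radians in [0, 2*pi).

#' Monte Carlo geometry
#'
#' Homogeneous cuboid with the source at the centre of the top face and
#' annular detectors on the top surface, matching a reflectance FD-NIRS
#' probe. The top face carries the tissue-air refractive-index mismatch;
#' side and bottom faces absorb escaping photons.
#'
#' @param cube_side Cube side length (cm).
#' @param detector_radii Nominal source-detector separations (cm).
#' @param annulus_width Radial width of each annular detector (cm).
#' @param g Scattering anisotropy factor, `0 <= g < 1`.
#' @param n_medium,n_outside Refractive indices inside/outside the medium.
#' @return Object of class `mc_geometry`.
#' @export
#' @examples
#' mc_geometry()
mc_geometry <- function(cube_side = 10, detector_radii = c(2, 2.5, 3, 3.5),
                        annulus_width = 0.1, g = 0.85, n_medium = 1.37,
                        n_outside = 1.0) {
  if (g < 0 || g >= 1) stop("anisotropy g must satisfy 0 <= g < 1")
  if (any(detector_radii + annulus_width / 2 >= cube_side / 2)) {
    stop("detector annuli must fit inside the top face")
  }
  if (any(diff(sort(detector_radii)) < annulus_width)) {
    stop("detector annuli overlap")
  }
  structure(list(cube_side = cube_side, detector_radii = detector_radii,
                 annulus_width = annulus_width, g = g, n_medium = n_medium,
                 n_outside = n_outside),
            class = "mc_geometry")
}

#' Simulate time-resolved reflectance (TPSF) at each detector
#'
#' Random-walk Monte Carlo with exponential free paths
#' (`mu_s = mu_s'/(1-g)`), Henyey-Greenstein scattering, Fresnel
#' reflection at the top boundary and absorbing side/bottom faces.
#' Absorption is applied as a continuous weight `exp(-mu_a * v * t)`
#' evaluated at each bin-centre time, so a run with `mu_a > 0` equals the
#' matching `mu_a = 0` run (same seed) scaled bin-wise by that factor.
#' Detected photons are binned by total time of flight
#' `t = pathlength * n_medium / c0`.
#'
#' @param mu_a,mu_s_prime Single-wavelength absorption / reduced scattering
#'   coefficients (cm^-1).
#' @param geom An [mc_geometry()].
#' @param n_photons Photon budget (0 gives all-zero TPSFs).
#' @param seed Integer seed for reproducibility (the R RNG is used; the
#'   caller's RNG state is restored on exit).
#' @param bin_width,window Temporal bin width and acquisition window (s).
#' @param wavelength Optional wavelength label (nm) carried in the output.
#' @return A list of `tpsf` objects, one per detector radius. Each has
#'   fields `bin_width`, `window`, `times` (bin centres, s), `weights`,
#'   `detector_radius`, `wavelength`, `n_photons`, `seed`, `mu_a`,
#'   `mu_s_prime`, and an `accounting` attribute with the weight ledger
#'   (`w_top`, `w_side`, `w_expired`; these sum to `n_photons`).
#' @export
#' @examples
#' tp <- simulate_tpsf(0.1, 10, mc_geometry(), n_photons = 5000, seed = 1)
#' sum(tp[[1]]$weights)
simulate_tpsf <- function(mu_a, mu_s_prime, geom = mc_geometry(),
                          n_photons, seed = NULL, bin_width = 10e-12,
                          window = 10e-9, wavelength = NA_real_) {
  stopifnot(inherits(geom, "mc_geometry"), n_photons >= 0,
            mu_a >= 0, mu_s_prime > 0, bin_width > 0, window > bin_width)
  v <- .c0_cm_ns / geom$n_medium * 1e9          # cm/s
  n_bins <- as.integer(round(window / bin_width))
  times <- (seq_len(n_bins) - 0.5) * bin_width  # bin centres
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  if (n_photons == 0) {
    res <- list(det = integer(0), path = numeric(0),
                w_top = 0, w_side = 0, w_expired = 0)
  } else {
    mu_s <- mu_s_prime / (1 - geom$g)
    res <- .mc_walk_cpp(mu_s, geom$g, geom$n_medium, geom$n_outside,
                        geom$cube_side, geom$detector_radii,
                        geom$annulus_width, window * v, n_photons)
  }
  absorb <- exp(-mu_a * v * times)              # per-bin absorption factor
  lapply(seq_along(geom$detector_radii), function(d) {
    sel <- res$det == d
    t_d <- res$path[sel] / v
    bins <- pmin(floor(t_d / bin_width) + 1L, n_bins)
    w <- numeric(n_bins)
    if (length(bins)) {
      counts <- tabulate(bins, nbins = n_bins)
      w <- counts * absorb
    }
    structure(
      list(bin_width = bin_width, window = window, times = times,
           weights = w, detector_radius = geom$detector_radii[d],
           wavelength = wavelength, n_photons = n_photons, seed = seed,
           mu_a = mu_a, mu_s_prime = mu_s_prime),
      accounting = list(w_top = res$w_top, w_side = res$w_side,
                        w_expired = res$w_expired),
      class = "tpsf")
  })
}

#' Frequency-domain quantities from a TPSF
#'
#' Evaluates the temporal transform directly at the modulation frequency
#' (which need not be a grid frequency of the 10 ps / 10 ns sampling):
#' `S(f) = sum_k w_k * exp(-i * 2*pi*f * t_k) * dt` over bin centres `t_k`.
#' Returns `dc = S(0)`, `ac = |S(f)|` and `phase = -Arg S(f)` wrapped to
#' `[0, 2*pi)` (positive lag convention).
#'
#' @param tpsf A `tpsf` object from [simulate_tpsf()].
#' @param f_mod Modulation frequency (Hz).
#' @param sample_id Optional sample label carried into the output row.
#' @return One-row data frame with columns `sample_id`, `wavelength_nm`,
#'   `rho_cm`, `f_mod_hz`, `dc`, `ac`, `phase_rad`.
#' @export
#' @examples
#' tp <- simulate_tpsf(0.1, 10, mc_geometry(), n_photons = 2e4, seed = 1)
#' fd_from_tpsf(tp[[1]])
fd_from_tpsf <- function(tpsf, f_mod = 110e6, sample_id = NA) {
  stopifnot(inherits(tpsf, "tpsf"))
  w <- tpsf$weights
  if (all(w == 0)) {
    stop("TPSF has zero total weight: phase is undefined")
  }
  dt <- tpsf$bin_width
  s <- sum(w * exp(-2i * pi * f_mod * tpsf$times)) * dt
  phase <- (-Arg(s)) %% (2 * pi)
  data.frame(sample_id = sample_id, wavelength_nm = tpsf$wavelength,
             rho_cm = tpsf$detector_radius, f_mod_hz = f_mod,
             dc = sum(w) * dt, ac = Mod(s), phase_rad = phase)
}

#' Monte Carlo forward model for a cohort of tissue samples
#'
#' Runs one Monte Carlo simulation per (sample, wavelength) -- each run
#' serves every detector radius -- and extracts DC/AC/phase at the
#' modulation frequency.
#'
#' @param samples A list of tissue samples from [generate_cohort()].
#' @param geom An [mc_geometry()].
#' @param wavelengths Wavelengths (nm) to simulate; must be present in each
#'   sample's optical-property table.
#' @param n_photons Photon budget per (sample, wavelength). Budgets below
#'   1e5 trigger a low-photon warning.
#' @param f_mod Modulation frequency (Hz).
#' @param seed Integer seed; per-run sub-seeds are derived deterministically.
#' @return FD measurement table: data frame with columns `sample_id`,
#'   `wavelength_nm`, `rho_cm`, `f_mod_hz`, `dc`, `ac`, `phase_rad`.
#' @export
forward_cohort_mc <- function(samples, geom = mc_geometry(),
                              wavelengths = fd_wavelengths("eight"),
                              n_photons = 2e5, f_mod = 110e6, seed = 1) {
  if (n_photons < 1e5) {
    warning("photon budget below 1e5: FD phases will be noisy")
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max,
                          length(samples) * length(wavelengths))
  run <- 0L
  rows <- list()
  for (s in samples) {
    op <- s$optics
    for (wl in wavelengths) {
      run <- run + 1L
      j <- match(wl, op$wavelength_nm)
      if (is.na(j)) stop("sample ", s$id, " has no optics at ", wl, " nm")
      tps <- simulate_tpsf(op$mu_a[j], op$mu_s_prime[j], geom, n_photons,
                           seed = sub_seeds[run], wavelength = wl)
      rows[[length(rows) + 1L]] <- do.call(
        rbind, lapply(tps, fd_from_tpsf, f_mod = f_mod, sample_id = s$id))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.tpsf <- function(x, ...) {
  cat(sprintf(
    "TPSF: rho %.2f cm, %d bins x %.0f ps, detected weight %.4g / %g photons\n",
    x$detector_radius, length(x$weights), x$bin_width * 1e12,
    sum(x$weights), x$n_photons))
  invisible(x)
}

#' Write / read a TPSF as columnar text
#'
#' Plain-text exchange format: `# key=value` header lines (seed, photon
#' budget, optics, detector radius) followed by two columns `time_ps` and
#' `weight`.
#'
#' @param tpsf A `tpsf` object.
#' @param path File path.
#' @return `write_tpsf` returns `path` invisibly; `read_tpsf` returns a
#'   `tpsf` object.
#' @export
write_tpsf <- function(tpsf, path) {
  stopifnot(inherits(tpsf, "tpsf"))
  hdr <- c(
    sprintf("# seed=%s", format(tpsf$seed)),
    sprintf("# n_photons=%s", format(tpsf$n_photons)),
    sprintf("# mu_a=%.10g", tpsf$mu_a),
    sprintf("# mu_s_prime=%.10g", tpsf$mu_s_prime),
    sprintf("# detector_radius=%.10g", tpsf$detector_radius),
    sprintf("# wavelength=%s", format(tpsf$wavelength)),
    sprintf("# bin_width_s=%.10g", tpsf$bin_width),
    sprintf("# window_s=%.10g", tpsf$window),
    "time_ps weight")
  body <- sprintf("%.6g %.12g", tpsf$times * 1e12, tpsf$weights)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_tpsf
#' @param path File path.
#' @export
read_tpsf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, regmatches(hdr, regexec("^# ([^=]+)=(.*)$", hdr)))
  meta <- setNames(as.list(kv[, 3]), kv[, 2])
  d <- read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  num <- function(k) suppressWarnings(as.numeric(meta[[k]]))
  structure(
    list(bin_width = num("bin_width_s"), window = num("window_s"),
         times = d$time_ps * 1e-12, weights = d$weight,
         detector_radius = num("detector_radius"),
         wavelength = num("wavelength"), n_photons = num("n_photons"),
         seed = num("seed"), mu_a = num("mu_a"),
         mu_s_prime = num("mu_s_prime")),
    class = "tpsf")
}
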