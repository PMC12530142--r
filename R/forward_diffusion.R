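# Closed-form frequency-domain forward model for a photon-density wave in a
# highly scattering medium. All functions are vectorized over mu_a/mu_s'.
# Units: mu_a, mu_s', k in cm^-1; rho in cm; f_mod in Hz; v in cm/s;
# phase in radians (positive lag).

#' Frequency-domain measurement context
#'
#' Bundles the modulation frequency, refractive index and source-detector
#' separation used by the diffusion forward model. The angular frequency
#' `omega = 2*pi*f_mod` (rad/s) and the speed of light in the medium
#' `v = c0/n_medium` (cm/s) are derived.
#'
#' @param rho Source-detector separation (cm, >= 0).
#' @param f_mod Modulation frequency (Hz, >= 0; 0 gives the DC limit).
#' @param n_medium Refractive index of the medium.
#' @return Object of class `fd_context`.
#' @export
#' @examples
#' fd_context(rho = 2)
fd_context <- function(rho, f_mod = 110e6, n_medium = 1.37) {
  stopifnot(rho >= 0, f_mod >= 0, n_medium > 0)
  v <- .c0_cm_ns / n_medium * 1e9
  structure(list(rho = rho, f_mod = f_mod, omega = 2 * pi * f_mod,
                 n_medium = n_medium, v = v),
            class = "fd_context")
}

#' Complex diffusion wavevector
#'
#' Attenuation (`k_real`) and oscillatory (`k_imag`) parts of the
#' photon-density-wave wavevector in the diffusion approximation, with
#' diffusion coefficient `D = 1/(3*(mu_a + mu_s'))`:
#' \deqn{k_{r,i} = \sqrt{\frac{\mu_a}{2D}\left(\sqrt{1 +
#'   (\omega/(v\mu_a))^2} \pm 1\right)}.}
#' They satisfy `k_real * k_imag = omega/(2 v D)` and
#' `k_real^2 - k_imag^2 = mu_a / D`; at `omega = 0`, `k_imag = 0` and
#' `k_real = sqrt(mu_a / D)` (the effective attenuation coefficient).
#'
#' @param mu_a Absorption coefficient(s) (cm^-1, > 0).
#' @param mu_s_prime Reduced scattering coefficient(s) (cm^-1, > 0).
#' @param ctx An [fd_context()].
#' @return List with vectors `k_real`, `k_imag` (cm^-1) and `D` (cm).
#' @export
#' @examples
#' wavevector(0.1, 10, fd_context(rho = 2))
wavevector <- function(mu_a, mu_s_prime, ctx) {
  stopifnot(inherits(ctx, "fd_context"))
  if (any(mu_a <= 0)) stop("mu_a must be > 0 for the FD wavevector")
  if (any(mu_s_prime <= 0)) stop("mu_s_prime must be > 0")
  D <- 1 / (3 * (mu_a + mu_s_prime))
  base <- mu_a / (2 * D)
  root <- sqrt(1 + (ctx$omega / (ctx$v * mu_a))^2)
  list(k_real = sqrt(base * (root + 1)),
       k_imag = sqrt(base * (root - 1)),
       D = D)
}

#' Phase of the detected photon-density wave
#'
#' Phase lag accumulated by an intensity-modulated photon-density wave over a
#' source-detector separation `rho`:
#' \deqn{\Phi = k_i \rho - \arctan\!\left(\frac{k_i \rho}{1 + k_r \rho}\right),}
#' the detected-flux phase of the `(1 + k rho) exp(-k rho)/rho^2`-type
#' spherical-wave solution. `Phi >= 0`, vanishing at `rho = 0` and at zero
#' modulation frequency.
#'
#' @inheritParams wavevector
#' @return Phase(s) in radians (positive lag).
#' @export
#' @examples
#' flux_phase(0.1, 10, fd_context(rho = 2))
flux_phase <- function(mu_a, mu_s_prime, ctx) {
  k <- wavevector(mu_a, mu_s_prime, ctx)
  rho <- ctx$rho
  k$k_imag * rho - atan(k$k_imag * rho / (1 + k$k_real * rho))
}

#' Model AC/DC amplitude at a source-detector separation
#'
#' Asymptotic spherical-wave amplitude `U = exp(-k_real * rho) / rho^2`, for
#' which `log(rho^2 * U)` is exactly linear in `rho` with slope `-k_real` --
#' the form assumed by the multidistance slope method. `component = "dc"`
#' evaluates the same expression at zero modulation frequency. Amplitudes are
#' in arbitrary units (no source-power calibration).
#'
#' @inheritParams wavevector
#' @param component `"ac"` (at `ctx$f_mod`) or `"dc"` (zero frequency).
#' @return Amplitude(s), arbitrary units.
#' @export
#' @examples
#' model_amplitude(0.1, 10, fd_context(rho = 2.5))
model_amplitude <- function(mu_a, mu_s_prime, ctx,
                            component = c("ac", "dc")) {
  component <- match.arg(component)
  stopifnot(inherits(ctx, "fd_context"))
  if (ctx$rho <= 0) stop("rho must be > 0 for the amplitude model")
  if (component == "dc") {
    ctx <- fd_context(ctx$rho, f_mod = 0, n_medium = ctx$n_medium)
  }
  k <- wavevector(mu_a, mu_s_prime, ctx)
  exp(-k$k_real * ctx$rho) / ctx$rho^2
}
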