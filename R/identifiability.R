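# Linearized identifiability analysis of the phase-only inversion: how much
# information multispectral single-distance phase data carry about each
# parameter, given the measurement noise and the population variability.

#' Linear-Gaussian recovery bound for the phase-only inversion
#'
#' Linearizes the phase forward model around a reference parameter vector
#' and treats the population variability as a Gaussian prior to compute the
#' posterior standard deviation of each parameter -- the accuracy that an
#' ideal (Bayes-optimal) estimator could achieve given phases with additive
#' Gaussian noise. The implied best-case mean absolute error is
#' `sqrt(2/pi) * sd`. Because the bound uses the generating population
#' itself as the prior, no estimator evaluated on that population can have
#' a lower mean error; parameter/noise combinations whose bound exceeds a
#' desired accuracy are unidentifiable at that accuracy, whatever the
#' algorithm.
#'
#' Also returns the singular values of the bound-scaled phase Jacobian:
#' values far below the leading one flag near-degenerate parameter
#' combinations (for this model, a joint rescaling of absorption and
#' scattering leaves single-frequency phases almost unchanged).
#'
#' @param wavelengths Wavelengths (nm).
#' @param rho Source-detector separation (cm).
#' @param noise_sd Phase noise standard deviation (radians).
#' @param theta0 Reference parameter vector (defaults to the representative
#'   tissue values used by the cohort generator).
#' @param prior_sd Named prior standard deviations in physical units
#'   (defaults to the cohort generator's perturbations: 10% of the mean
#'   concentrations, 1% of the scattering parameters).
#' @param config An [fd1sd_config()].
#' @return List with `posterior_sd`, `prior_sd`, `best_mae` (all named, in
#'   physical units), `best_mre` (percent of `theta0`), and
#'   `singular_values` of the scaled Jacobian.
#' @export
#' @examples
#' phase_recovery_bound(fd_wavelengths("eight"), rho = 2,
#'                      noise_sd = 0.0035)
phase_recovery_bound <- function(wavelengths, rho, noise_sd,
                                 theta0 = c(hbo = 60, hb = 25,
                                            cco_redox = 8.5, a = 24.2,
                                            b = 1.611),
                                 prior_sd = NULL,
                                 config = fd1sd_config()) {
  stopifnot(noise_sd > 0)
  mode <- if ("cco_redox" %in% names(theta0)) "eight" else "two"
  if (is.null(prior_sd)) {
    prior_sd <- 0.1 * theta0
    prior_sd[c("a", "b")] <- 0.01 * theta0[c("a", "b")]
  }
  prior_sd <- prior_sd[names(theta0)]
  J <- phase_model(theta0, wavelengths, rho, config, mode,
                   jacobian = TRUE)$jacobian
  fisher <- crossprod(J) / noise_sd^2
  post <- solve(fisher + diag(1 / prior_sd^2))
  post_sd <- sqrt(diag(post))
  b <- fd1sd_bounds(mode)
  sv <- svd(J %*% diag(b$half_width))$d
  list(posterior_sd = setNames(post_sd, names(theta0)),
       prior_sd = prior_sd,
       best_mae = setNames(sqrt(2 / pi) * post_sd, names(theta0)),
       best_mre = setNames(sqrt(2 / pi) * post_sd / theta0 * 100,
                           names(theta0)),
       singular_values = sv)
}
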