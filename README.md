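# fdphase

Absolute quantification of tissue chromophores from frequency-domain
near-infrared spectroscopy (FD-NIRS), using **phase measurements at a
single source–detector separation and a single modulation frequency**.
The package is aimed at biomedical-optics researchers who want to study —
with full control over the forward physics — whether oxyhaemoglobin
(HbO), deoxyhaemoglobin (Hb) and the cytochrome-c-oxidase redox-state
difference (CCOredox) can be recovered without the multidistance,
amplitude-calibrated hardware that the conventional slope method needs.

It provides the complete simulation-and-inversion chain:

* **Spectral models** — Beer–Lambert absorption
  `mu_a(lambda) = sum_i eps_i(lambda) C_i + w mu_a,water(lambda)` with a
  fixed 75% water background, power-law scattering
  `mu_s'(lambda) = a (lambda/lambda0)^(-b)`, and least-squares unmixing
  (`absorption_spectrum()`, `scattering_spectrum()`,
  `unmix_concentrations()`).
* **Closed-form forward model** — photon-density-wave phase
  `Phi = k_i rho - atan(k_i rho / (1 + k_r rho))` with
  `k_{r,i} = sqrt((mu_a/2D)(sqrt(1+(omega/v mu_a)^2) +/- 1))`,
  `D = 1/(3(mu_a+mu_s'))` (`flux_phase()`, `wavevector()`,
  `model_amplitude()`).
* **Time-resolved Monte Carlo** — compiled photon transport in a 10-cm
  cube (Henyey–Greenstein scattering, g = 0.85, Fresnel top boundary,
  n = 1.37), 10 ps binning over 10 ns, and off-grid Fourier extraction of
  DC/AC/phase at 110 MHz (`simulate_tpsf()`, `fd_from_tpsf()`).
* **Multidistance slope method** baseline (`fit_slopes()`,
  `slopes_to_optics()`, `slope_pipeline()`).
* **The single-distance, phase-only estimator** `fit_fd1sd()`: bounded
  L-BFGS-B minimization of the summed squared phase residuals plus an
  edge-barrier penalty `R(theta) = sum_j alpha_j ((theta_j - c_j)/h_j)^2`
  centred on the physiological parameter box, with analytic gradients.
* **Cohort studies** — synthetic populations, MAE/MRE evaluation and a
  one-call method comparison (`generate_cohort()`, `run_experiment()`),
  plus a linear-Gaussian identifiability bound
  (`phase_recovery_bound()`).

## Worked example

Generate noiseless eight-wavelength phases for a known tissue, then
recover the tissue from the phases alone at a single 2-cm separation:

```r
library(fdphase)
wl <- fd_wavelengths("eight")          # 784 ... 894 nm
truth <- c(hbo = 63, hb = 24, cco_redox = 9.1, a = 24.2, b = 1.611)
cfg <- fd1sd_config()
ph <- phase_model(truth, wl, rho = 2, config = cfg, mode = "eight")$phase
round(ph, 4)
#> [1] 0.3469 0.3391 0.3225 0.3057 0.2935 0.2845 0.2761 0.2695
fit_fd1sd(ph, wl, rho = 2, mode = "eight", config = cfg)
#> FD phase-only fit (eight-wavelength mode, rho = 2.00 cm)
#>       hbo        hb cco_redox         a         b
#>   63.0567   24.0018    9.0942   24.2009    1.6105
#> cost 1.478e-09 (data 7.790e-13 + reg 1.477e-09), converged after 145 evaluations
```

The phases (radians, a ~0.27–0.35 rad lag at 110 MHz) fall with
wavelength because scattering does; the fit recovers all five parameters
— three chromophore concentrations in µM plus the two scattering-law
parameters — to a fraction of a percent from eight noiseless numbers.

How far this can be pushed under measurement noise is a question of
information, not optimization. The package computes the corresponding
bound:

```r
round(phase_recovery_bound(wl, rho = 2, noise_sd = 0.0035)$best_mre, 2)
#>       hbo        hb cco_redox         a         b
#>      3.71      6.77      7.55      0.78      0.78
```

i.e. with 0.0035 rad of phase noise, even an ideal estimator equipped
with the population statistics cannot beat ~3.7% mean relative error for
HbO or ~7.6% for CCOredox at 2 cm — a consequence of the near-degenerate
`mu_s'/mu_a` scale direction of single-frequency phase data. See the
vignette (`vignettes/fd1sd-phase.Rmd`) for the analysis and its
consequences for the shipped defaults.

The Monte Carlo forward chain cross-checks the analytic model
(2e5 photons, `mu_a` = 0.1, `mu_s'` = 10 cm⁻¹, 2 cm, 110 MHz):

```r
tp <- simulate_tpsf(0.1, 10, mc_geometry(), n_photons = 2e5, seed = 1)
fd_from_tpsf(tp[[1]])$phase_rad        # 0.4284
flux_phase(0.1, 10, fd_context(2))     # 0.4237
```

A thin command-line front end is installed with the package
(`inst/scripts/fdphase`) for shell-driven runs:
`fdphase report --mode eight --seed 1 --out runs/demo` writes the cohort
truth, measurements, slope and phase-only results and the MAE/MRE error
report as CSV.

## Acceptance script

`scripts/acceptance.R` regenerates the full scaled-down replication from
scratch: a 30-sample cohort, closed-form surrogate phases (0.0035 rad
Gaussian noise for the eight-wavelength protocol, noiseless for the
two-wavelength one), independent phase-only fits at 2.0/2.5/3.0 cm, and
MAE/MRE of the recovered concentrations. Run it from the repository root
against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It writes one JSON object with a numeric `value` (µM for MAEs, percent
for MREs) and the cohort size `n` per reported quantity.
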