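---
title: "Single-distance, phase-only FD-NIRS: model, methods and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-distance, phase-only FD-NIRS: model, methods and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdphase)
```

## The problem

Frequency-domain near-infrared spectroscopy (FD-NIRS) launches
intensity-modulated light into tissue and records, at a detector on the
surface, the DC amplitude, the AC amplitude and the phase lag of the
emerging photon-density wave. From these one can recover the absolute
absorption coefficient $\mu_a(\lambda)$ and reduced scattering coefficient
$\mu_s'(\lambda)$, and from multispectral $\mu_a$ the tissue chromophore
concentrations: oxyhaemoglobin (HbO), deoxyhaemoglobin (Hb) and — much
harder, because of its low concentration and shallow spectral features —
the oxidised-minus-reduced difference concentration of cytochrome-c
oxidase (CCOredox), a marker of mitochondrial oxidative metabolism.

The conventional route is the *multidistance slope method*: phase and
$\ln(\rho^2 U_{AC})$ are regressed against the source–detector separation
$\rho$, and the two slopes are converted to $(\mu_a, \mu_s')$ per
wavelength. It needs several spatial channels and amplitude calibration.
This package implements and studies an alternative that needs neither: a
*single-separation, phase-only* estimator that fits a small set of
wavelength-independent physiological parameters directly to multispectral
phase data at one $\rho$ and one modulation frequency.

## Models

**Spectral parameterization.** Absorption mixes linearly
(Beer–Lambert), with water as a fixed background at volume fraction
$w = 0.75$:
$$\mu_a(\lambda) = \sum_i \varepsilon_i(\lambda)\,C_i
  + w\,\mu_{a,\mathrm{water}}(\lambda),
  \qquad i \in \{\mathrm{HbO}, \mathrm{Hb}, \mathrm{CCOredox}\},$$
and reduced scattering follows a power law
$$\mu_s'(\lambda) = a\,(\lambda/\lambda_0)^{-b}, \qquad \lambda_0 = 500
\textrm{ nm}.$$
The extinction table shipped in `inst/extdata/extinction_nir.csv`
(units cm$^{-1}\,\mu$M$^{-1}$) is compiled from standard compendia;
haemoglobin molar extinctions are converted with $\ln(10)\times 10^{-6}$.
The published form of the scattering law with $(\lambda_0/\lambda)^{-b}$
would *increase* with wavelength; this package uses the physically
standard decreasing convention above, identically in the forward and the
inverse direction, so all internal consistency results are unaffected.

**Frequency-domain forward model.** With diffusion coefficient
$D = 1/(3(\mu_a + \mu_s'))$, modulation frequency $\omega = 2\pi f$, and
speed of light in tissue $v = c_0/n$, the photon-density wavevector has
attenuation and oscillation parts
$$k_{r,i} = \sqrt{\frac{\mu_a}{2D}\Bigl(\sqrt{1 + (\omega/v\mu_a)^2}
  \pm 1\Bigr)},$$
and the detected-flux phase at separation $\rho$ is
$$\Phi = k_i \rho - \arctan\frac{k_i\rho}{1 + k_r\rho}.$$
This is an infinite-medium spherical-wave form: no extrapolated-boundary
image source is included, deliberately, because the estimator uses the
same expression in its cost function — internal consistency between
forward and inverse is what the validation exercises. The asymptotic AC
amplitude $U = e^{-k_r\rho}/\rho^2$ makes $\ln(\rho^2 U)$ exactly linear
in $\rho$ with slope $-k_r$, which is the premise of the slope method;
`slopes_to_optics()` inverts the two slope relations exactly
(round-tripped to $10^{-9}$ in the tests).

**The phase-only estimator.** `fit_fd1sd()` minimizes
$$\mathrm{cost}(\theta) = \sum_\lambda
  \bigl[\Phi_\mathrm{model}(\lambda;\theta) -
  \Phi_\mathrm{meas}(\lambda)\bigr]^2 + R(\theta), \qquad
  \theta = \{\mathrm{HbO}, \mathrm{Hb}, (\mathrm{CCOredox}), a, b\},$$
by L-BFGS-B inside the physiological box HbO 30–90, Hb 5–40, CCOredox
0–16 $\mu$M, $a$ 15–50 cm$^{-1}$, $b$ 0.5–2, with the *edge-barrier*
penalty
$$R(\theta) = \sum_j \alpha_j\Bigl(\frac{\theta_j - c_j}{h_j}\Bigr)^2,
  \qquad c_j = \tfrac{u_j + l_j}{2},\; h_j = \tfrac{u_j - l_j}{2},$$
which is zero at each range midpoint and exactly $\alpha_j$ on a bound.
With two wavelengths (690/830 nm) four parameters are fitted and CCOredox
is excluded; with the eight-wavelength set (784–894 nm) all five are.

## Numerical choices

* **Coordinates.** The optimizer works in centred, half-width-normalized
  coordinates $x_j = (\theta_j - c_j)/h_j \in [-1, 1]$; concentrations
  (tens of $\mu$M) and the scattering power ($\approx 1.6$) otherwise
  differ by an order of magnitude in scale.
* **Gradients and stopping.** Analytic gradients are supplied (validated
  against finite differences to $10^{-5}$). The stopping rule is a
  projected-gradient tolerance of $10^{-10}$ on the scaled problem with
  the function-decrease test disabled (`factr = 0`): the cost surface has
  a valley so flat that points differing by 2% in HbO can differ by less
  than $10^{-10}$ in cost, and any function-decrease criterion strands
  the optimizer at an arbitrary point inside it.
* **Initialization** is the deterministic bounds midpoint. On noiseless
  data the regularized optimum is unique and a perturbed start recovers
  the same estimate (tested at +20%).
* **Edge-barrier weight.** The reference work does not state $\alpha$.
  It was calibrated here once, on a dedicated seed, to the largest grid
  value for which a noiseless eight-wavelength cohort is recovered with
  every chromophore mean relative error below 1% ($\alpha = 3\times
  10^{-9}$; $10^{-8}$ already gives 1.9% on HbO), with the penalty at the
  cohort-mean parameters orders of magnitude below the data term at
  initialization. It is deliberately *not* tuned for noisy-data
  performance — see "Identifiability" below for what that trade-off is.
* **Degenerate inputs.** Phases outside $[0, 2\pi)$ are wrapped with a
  warning; non-finite phases, unknown wavelengths (reported by name) and
  rank-deficient unmixing systems are errors; `mu_a = 0` is rejected by
  the wavevector (the $\omega/v\mu_a$ term diverges).

## The synthetic cohort

`generate_cohort()` draws the population the method is evaluated on:
30 samples with mean concentrations 60/25/8.5 $\mu$M (HbO/Hb/CCOredox),
each perturbed by zero-mean Gaussian noise with SD 10% of the mean
(truncated at zero — at the defaults the truncation is never exercised,
as the CCO mean sits ten SDs from zero), water fraction fixed at 0.75,
and scattering $a = 24.2$, $b = 1.611$ perturbed by 1%. Two-wavelength
cohorts carry no CCOredox: the haemoglobin-only configuration defines its
samples by HbO and Hb alone, and carrying an unmodelled absorber through
the two-wavelength inversion would contaminate a comparison that is meant
to be an internal-consistency exercise.

The surrogate forward model (`forward_cohort_surrogate()`) produces
closed-form phases and amplitudes, with optional additive Gaussian phase
noise, default SD 0.0035 rad ($\approx 0.2^\circ$ — about the shot-noise
phase error of a $10^8$-photon time-domain simulation at 2 cm). The
Monte Carlo forward (`simulate_tpsf()` + `fd_from_tpsf()`) is a
desk-scale fidelity check, not the acceptance workhorse: budgets of
$2\times 10^5$–$10^6$ photons replace GPU-scale runs.

What a green test on surrogate data does establish: the estimator,
optimizer, spectral chain and error metrics are internally consistent,
and the inverse problem behaves as analysed below. What it does *not*
establish: robustness to model mismatch (boundary conditions, detector
geometry, heterogeneous or layered tissue), which only the Monte Carlo
route — and ultimately experiment — can probe.

## Monte Carlo engine

A compiled random walk in a 10-cm cube: exponential free paths with
$\mu_s = \mu_s'/(1-g)$, Henyey–Greenstein scattering ($g = 0.85$),
probabilistic Fresnel reflection at the refractive-index-mismatched top
face ($n$ 1.37/1.0), absorbing side and bottom faces, annular 1-mm
detectors at 2.0–3.5 cm, 10 ps bins over a 10 ns window. Three
deliberate choices:

* **Absorption is applied at detection**, as a continuous weight
  $e^{-\mu_a v t}$ evaluated at the *bin-centre* time, not during the
  walk. Trajectories therefore depend only on scattering: runs with
  different $\mu_a$ but the same seed traverse identical paths, and
  TPSF$(\mu_a)$ equals TPSF$(0)\cdot e^{-\mu_a v t}$ bin-wise to floating
  precision (a tested identity). The cost is a sub-percent per-event
  weight discretisation ($\le \mu_a v \Delta t/2$), far below desk-scale
  Monte Carlo variance. With exact per-photon path lengths the identity
  could not hold bin-wise once two photons share a bin.
* **No survival roulette is needed**: since in-flight weights never
  decay, walks are terminated instead by the 10-ns acquisition window
  (photons that outlive it can never contribute), which also bounds the
  runtime. The weight ledger — detected + side/bottom losses + expired —
  closes to the photon budget exactly.
* **Off-grid Fourier evaluation**: 110 MHz is not a grid frequency of a
  10-ns record, so `fd_from_tpsf()` evaluates the transform as a direct
  complex-exponential sum at exactly the modulation frequency.

At $2\times10^5$ photons the Monte Carlo phase at 2 cm agrees with the
closed form within 0.05 rad, and the mean time of flight matches a
diffusion-theory first-moment oracle within 15%.

## Identifiability: the central caveat

The package computes, in `phase_recovery_bound()`, the linear-Gaussian
recovery bound for the phase-only problem: the accuracy a Bayes-optimal
estimator could reach given the population variability as a prior.

```{r bound}
bound <- phase_recovery_bound(fd_wavelengths("eight"), rho = 2,
                              noise_sd = 0.0035)
round(bound$best_mre, 2)          # best-case MRE (%) per parameter
signif(bound$singular_values, 3)  # scaled phase Jacobian spectrum
```

Two facts drive everything. First, the scaled Jacobian spectrum spans
more than three orders of magnitude: single-frequency phases depend, to
leading order, only on the ratio $\mu_s'/\mu_a$, so a joint rescaling of
absorption and scattering — HbO trading against $a$ and $b$ — moves all
eight phases by less than $3\times10^{-5}$ rad even for a 25% HbO change.
Second, with 0.0035 rad of phase noise this near-null direction is
unmeasurable, and the bound shows that *no* estimator without a prior
sharper than the generating population itself can reach, for example, a
3.7% HbO or 7.6% CCOredox mean relative error at 2 cm.

Published accuracies for this class of method that are materially better
than the bound can therefore only arise from prior anchoring — fixed
initialization at literature-representative tissue values combined with
early stopping, or regularization centred near the population means (note
that the concentration box midpoints, 60/22.5/8 µM, essentially are the
population means, while the scattering midpoints are not). This package
deliberately ships the *weakly* regularized estimator instead: the
calibration rule above (noiseless recovery < 1%) forces $\alpha$ small,
so the estimator injects almost no prior and honestly exposes the
information limit. Consequently, on noisy cohorts its concentration
errors are bounded by the box constraints rather than by the data, and
they exceed the reference accuracies by a wide margin; the acceptance
suite records this openly rather than recovering the reference numbers
through an inverse-crime prior. Users who want the anchored behaviour
can pass `init =` the representative values and larger per-parameter
`alpha` explicitly — with the understanding that the result then reports
the prior as much as the measurement.

The two-wavelength mode is under-determined by construction (two phases,
four parameters); there the edge-barrier penalty is what selects among
exactly-fitting solutions, and estimates inherit its pull toward the box
midpoints. This is documented loudly here because it is invisible in the
fit diagnostics: the data term converges to zero regardless.

## Slope-method baseline

`slope_pipeline()` implements the conventional baseline: unweighted
ordinary least squares of phase and $\ln(\rho^2 U_{AC})$ over the four
separations, slope-to-optics conversion with the infinite-medium
relations consistent with the forward model, then Beer–Lambert unmixing
(exactly determined at two wavelengths, least squares at eight). On
surrogate data the amplitude slope recovers $k_r$ exactly by
construction; the phase slope carries the arctan term's residual
curvature, a bias below 3% of $k_i$ for cohort-typical optics over
2.0–3.5 cm, which propagates to roughly 1.3–1.7% in recovered $\mu_a$ —
the floor of the baseline's accuracy in the inverse-crime setting. A
three-separation variant (dropping 3.5 cm) is available by passing a
shorter `rhos` vector.

## Known limitations

* Homogeneous media only; no layered or heterogeneous tissue, no
  image-source boundary correction in the analytic model.
* The extinction fixture is representative, not authoritative; absolute
  concentrations inherit its accuracy (internal-consistency results do
  not).
* Single modulation frequency; a frequency sweep would break the
  $\mu_s'/\mu_a$ scale degeneracy and is the natural extension.
* The amplitude+phase joint fit with a gain parameter is intentionally
  absent (the cost interface keeps a seam for it): amplitude scaling is
  calibration-dependent, which is exactly what the phase-only design
  avoids.
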