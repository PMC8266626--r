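---
title: "Models and methods behind replitrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind replitrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replitrace)
```

replitrace quantifies the behaviour of fluorescently labelled hexameric
helicases at DNA replication forks from single-molecule TIRF data: how many
complexes load onto DNA, how long a loaded helicase stays, whether it
exchanges with the solution pool, and how often additional helicases visit
an assembled replisome. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## The measurement chain

Every quantity the package reports descends from the same chain:

1. raw movies are corrected for camera offset and excitation-beam profile;
2. diffraction-limited foci are localised to sub-pixel precision and their
   background-subtracted intensities extracted;
3. intensities are converted to molecule copy numbers through a two-part
   calibration — the intensity of one fluorophore and the mean number of
   fluorophores per complex (degree of labelling, DOL);
4. copy-number or intensity time series feed the kinetic analyses.

Errors propagate down this chain, which is why the calibration stages get
their own estimators and tests.

## Photobleaching step counting

A surface-immobilised complex bleaches in discrete steps, one per dye.
`detect_steps()` segments a trace into piecewise-constant levels and counts
downward transitions. The engine is recursive binary segmentation under a
Bayesian information criterion for the piecewise-constant Gaussian model,

$$\mathrm{BIC}(m) = n \log(\mathrm{RSS}/n) + 2m\log n,$$

where each of the $m$ change points contributes two parameters (a location
and a new level). Three refinements matter in practice:

* after every proposed split, all change-point locations are re-optimised
  by coordinate descent (a greedy split that lands one frame off is
  otherwise locked in);
* a two-split lookahead catches short intermediate levels: when two dyes
  bleach within a few frames of each other, no *single* split improves the
  criterion even though the pair does. The lookahead window is
  `4 * min_segment` frames — pairs further apart are found by successive
  single splits;
* a final pruning pass removes any change point whose removal improves the
  criterion.

With these refinements the segmentation is empirically identical to
exhaustive enumeration of all change-point placements under the same
criterion on staircase traces (the test suite checks 100 random
staircases; enumeration covers up to one more change point than the greedy
search returned, since both searches must range over the same model
space). `min_segment` defaults to 3 frames; upward steps (blinking,
arrivals) are counted as change points but never as bleaching steps.

## Degree of labelling

The histogram of steps per molecule estimates the labelling distribution.
Two Poisson estimators ship side by side because detection conditions the
data: an unlabelled complex is invisible, so observed step counts are
zero-truncated.

* `fit_poisson_dol(counts)` — the plain MLE, the sample mean.
* `fit_poisson_dol(counts, zero_truncated = TRUE)` — solves
  $\lambda/(1-e^{-\lambda}) = \bar k$ by bisection (tolerance $10^{-8}$).

Neither is exact for this generator, which caps dyes at the six labelling
sites of the hexamer: the cap pulls the observable mean below $\lambda$,
and the zero-truncated inversion (which assumes an uncapped Poisson)
overcorrects. For a true $\lambda = 3.5$ capped at 6, the mean visible dye
count is 3.32; the plain estimator targets exactly that, the
zero-truncated one lands near 3.18. We therefore report the plain
estimate as the headline DOL and the zero-truncated one alongside.

Single-fluorophore intensity is calibrated by `calibrate_single_fluorophore()`
from last-step drops (preferred — immune to residual multi-dye
contamination) or raw single-molecule intensities, as a single-Gaussian
fit; a two-component description winning by more than 10 BIC flags the
calibration as suspect (e.g. bimodal input from aggregates).

## Stoichiometry and population fitting

`estimate_stoichiometry()` divides a focus's initial intensity — the mean
of its first `n_initial_frames = 3` frames, taken before appreciable
bleaching — by (single-fluorophore intensity × DOL). Copy numbers are
continuous; their population structure is resolved by
`fit_stoichiometry_mixture()`.

The mixture fitter has two modes:

* **free**: standard $k$-component Gaussian EM, 20 restarts from
  quantile-spread initial means (first restart deterministic, the rest
  jittered under a fixed seed), best log-likelihood kept, component sds
  floored at 0.01 copies and flagged when the floor binds;
* **constrained**: component means tied to integer multiples of a single
  fitted peak, $\mu_m = m\,\mu_1$ — what integer copy numbers dictate —
  optionally with $\sigma_m = \sigma\sqrt{m}$ (`scaled_sds = TRUE`),
  because the dye-count variances of $m$ independent hexamers add.

The free mode is the honest default when nothing is known. For loading
data it is, however, close to useless, and it is worth being explicit
about why: with a mean of ~3.3 dyes per hexamer, the *within-population*
spread of copy-number estimates is large (sd ≈ 0.3–0.8 copies for 1–3
hexamers), adjacent populations overlap heavily, and the unconstrained
maximum-likelihood solution drifts far from the integer means — no amount
of data fixes this, it is a property of the model. The constrained mode
with scaled sds is the physically-motivated estimator for this problem and
is what the acceptance analyses use. EM log-likelihood traces are stored
on the fit object and asserted non-decreasing in the tests.

## Focus detection, colocalisation, kymographs

`detect_foci()` thresholds local maxima at `median + min_snr × MAD` of the
frame and refines each candidate by least-squares 2-D Gaussian fitting in
an odd window (default 7 px), with sub-pixel centroids (0-based
coordinates, pixel centre at integer), fitted PSF width bounded to
[0.5, 3] px (fits outside are discarded and counted), and duplicate
detections within 1 px merged keeping the brighter focus. Localisation
error is below 0.2 px RMS at SNR ≥ 10 on simulated movies.

`integrated_intensity()` sums a disc and subtracts the annulus *median*
(robust to neighbouring spots) times the disc area. Foci whose annulus
leaves the frame are flagged `NA` and excluded downstream.

`colocalize()` matches two channels one-to-one, greedily by ascending
centroid distance within a 2 px radius (ties by lowest index). The pair
set is symmetric in channel order; the colocalised fraction is reported
relative to the first (reference) channel. The chance of coincidental
colocalisation follows

$$C = \frac{A_R}{A_{\mathrm{FOV}}} \times n,$$

with the focus area $A_R$ defaulting to the matching disc $\pi r^2$ and
$n$ the number of foci in the *other* channel. $A_R$ is configurable
because "focus area" admits several readings and published chance values
cannot be reproduced without knowing which was used; the Monte-Carlo
agreement of this formula with random-focus simulations is part of the
acceptance suite.

`make_kymograph()` samples each frame along a line by bilinear
interpolation, averaged across a perpendicular width — the standard
space-time visualisation of forks on flow-stretched DNA. A fork moving at
$v$ px/s appears as a stripe of slope $v$ (recovered within 5 % in the
tests).

## Kinetics

**Lifetimes.** Ensemble decays (the per-frame mean over aligned
trajectories) are fit to $A e^{-t/\tau}$ by nonlinear least squares
(`minpack.lm`), initialised from the first value and the $A/e$ crossing
time. Dissociation and photobleaching compete as independent exponentials,
so rates add:

$$\frac{1}{\tau_{\mathrm{obs}}} = \frac{1}{\tau_{\mathrm{off}}} +
\frac{1}{\tau_{\mathrm{bleach}}},$$

inverted by `bleach_corrected_lifetime()`. Offsets are off by default (a
fully bleaching/unbinding ensemble decays to zero); a flag enables them.

**Comparing lifetimes.** The asymptotic errors of an ensemble-curve fit
are far too small for group comparisons, because the residuals are
strongly correlated across frames — each molecule's bleaching is a random
path, so a 29-molecule ensemble deviates from its mean curve coherently,
not independently per frame. `compare_lifetimes()` therefore bootstraps at
the molecule level (resample trajectories, refit, 200 replicates) and
compares lifetimes by a z-test on bootstrap errors. This is the chase
logic: a chase arm indistinguishable from the bleach-only control means
photobleaching explains all signal loss (no exchange); genuine exchange at
≥ 0.2 min⁻¹ shortens the fitted lifetime far beyond the bootstrap error.

**Bleach-lifetime extrapolation.** Bleaching probability is taken
proportional to absorbed dose, so lifetimes scale inversely with
time-averaged dose (irradiance × duty cycle):
`extrapolate_bleach_lifetime()`. A 400 ms exposure once every 8 s (duty
0.05) extends the wall-clock fluorophore lifetime 20-fold over continuous
excitation — in the simulator this follows mechanically from advancing the
bleaching clock only during exposure windows.

**FRAP.** Recovery after a bleach pulse is fit to

$$I(t) = a\,e^{-t/\tau_b} + I_0\left(1 - e^{-t/\tau}\right),$$

with $a$ the bleach amplitude, $\tau_b$ the photobleaching time, $I_0$ the
steady-state copy number and $\tau$ the characteristic exchange time. All
parameters are bounded positive. The fit multi-starts over distinct
$(\tau_b, \tau)$ pairs: equal time constants make the two terms nearly
collinear and the Jacobian singular, and a starting amplitude of zero
leaves the solver unable to move $\tau_b$ at all (its Jacobian column
vanishes), so the starting $a$ is floored at 5 % of the data maximum.
Identifiability of $\tau_b$ requires observing a substantial fraction of
the bleach decay: in simulations with $\tau_b = 300$ s, a 10-minute
window biases the mean recovered $\tau_b$ upward by ~15 %, while a
15-minute window recovers all four parameters within 2 % — hence the
15-minute default in `scenario_frap()`.

**Binding events.** `detect_binding_events()` thresholds a trajectory at
half a molecule — 0.5 × (single-fluorophore intensity × DOL) — and counts
maximal above-threshold runs of at least `min_duration` frames (default
1). The binding frequency is events per minute of trajectory duration;
the bound fraction is the fraction of frames above threshold. Optional
hysteresis (an exit threshold below the entry threshold, e.g. 0.25
molecules) prevents noise around the entry level from chopping one
binding event into several; it is the recommended setting for noisy data
and is used in the acceptance analyses. The half-molecule threshold has an
intrinsic blind spot this package does not hide: a binder carrying a
single dye sits *below* half a typical molecule's intensity and is
detected only when noise lifts it across the threshold, so measured
frequencies sit a few percent below the generating rate even at good SNR.

## The synthetic-data generator

The generator exists so that every stage above is testable against known
truth. It emulates:

* dye counts per hexamer — truncated Poisson (`"tpois"`, the default) or
  Binomial(6, λ/6) (`"binomial"`, independent labelling of the six
  cysteine sites). The binomial model is the mechanistically faithful one
  for maleimide labelling and is underdispersed relative to Poisson; the
  loading scenario uses it because only underdispersed labelling produces
  the resolved integer populations such experiments show. The truncated
  Poisson matches how DOL is conventionally *fitted* and drives the DOL
  calibration scenario;
* per-dye photobleaching, exponential in **cumulative exposure time** —
  the bleaching clock stops between exposures, which is the mechanism by
  which intermittent excitation extends fluorophore lifetimes;
* stable binders with exponential dissociation and transient binders as
  alternating renewal (telegraph) processes. The generating event rate of
  a telegraph emitter is the closed-form renewal rate
  $1/(\text{mean unbound wait} + \text{mean dwell})$ — note this is
  *below* the on-rate from the unbound state whenever dwells are
  non-negligible, and recovery tests compare against the renewal rate;
* movies: emitters rendered as pixel-integrated isotropic 2-D Gaussian
  PSFs (σ default 1.3 px), uniform background, Poisson shot noise,
  electronic offset and Gaussian read noise; moving forks translate the
  emitter at constant velocity and are truncated with a warning at the
  field edge;
* trajectories: the dye-count signal plus a single Gaussian effective
  noise term (`read_noise_sd`), representing the total post-extraction
  noise. Shot noise is deliberately a movie-level effect only; this keeps
  trajectory-level oracles exact (zero noise settings give bit-exact
  traces) and is a good approximation for background-dominated
  single-molecule traces.

Not emulated, by design: EM-gain excess noise, optical aberrations,
drift, chromatic offsets, and the polymer dynamics of flow-stretched DNA.
Passing recovery tests on this generator therefore demonstrates the
*analysis* is correct and unbiased under the stated noise model — not that
the noise model captures every property of real movies.

Determinism: every generator function takes a seed (defaulting to the
config's) and restores the caller's RNG state; identical seed + config
gives byte-identical output, which the tests assert.

## Study-scale scenarios and their parameters

The `scenario_*()` functions pre-register the simulated study conditions
used by the tests and the acceptance script:

| scenario | key settings | rationale |
|---|---|---|
| `scenario_dol` | 260 molecules, λ = 3.5 capped at 6, per-dye SNR 8, bleach over ~200 frames of a 1000-frame trace | the red-channel calibration regime; long traces keep simultaneous-bleach step losses below ~5 % |
| `scenario_loading` | 606 foci, populations 1/2/3 hexamers at weights 0.55/0.30/0.15, binomial labelling, molecule-level SNR 10 | the loading-assay regime; weights chosen once as a plausibly decreasing occupancy |
| `scenario_lifetime` | 200 trajectories, τ_off 34.4 min, τ_bleach 60 min wall-clock, 400 ms / 8 s imaging, 120 min span | the stability-assay regime; span ≈ 5 observed lifetimes |
| `scenario_chase` | 29 chase + 667 control molecules, τ_bleach 4.8 min, 400 ms / 0.8 s imaging, 15 min span | the chase-assay regime at its published group sizes |
| `scenario_frap` | a = 2, τ_b = 300 s, I0 = 1, τ = 120 s, noise 0.1·I0, 15 min window | recovery-model self-consistency at realistic parameters |
| `scenario_association` | event rates 0.84 and 0.13 min⁻¹; dwells 30.7 s and 55 s (implied by bound fractions of 43 % and 12 % at those rates); 123 and 74 trajectories; 20 min at 2 Hz; per-dye SNR 8 | the association-assay regimes; dwell times derived from rate × bound-fraction arithmetic |

Each scenario's n is the published group size where one exists; durations
and frame rates are package choices stated here once and not revisited.

## Known limitations

* The constrained mixture's third population mean inherits three times the
  uncertainty of the fitted unit peak; at n ≈ 600 its single-study scatter
  is ~0.1–0.15 copies even with a correct model.
* The zero-truncated DOL estimator assumes an uncapped Poisson and
  overcorrects when the site cap binds; use the plain estimator for capped
  labelling.
* Binding-frequency estimates are biased a few percent low by sub-threshold
  single-dye binders; hysteresis mitigates splitting but cannot recover
  events that never cross the entry threshold.
* The greedy change-point search guarantees only empirical, not provable,
  equivalence to exhaustive enumeration; pathological traces outside the
  staircase family may differ.
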