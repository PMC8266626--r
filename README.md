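# replitrace

Single-molecule fluorescence analysis of replisome helicase dynamics.

Loading a replicative helicase onto DNA is the committed step of
replisome assembly, and what happens to that helicase afterwards — how
many copies load, how long they stay, whether they exchange with the
solution pool, how often extra helicases visit the replisome — is
measurable one molecule at a time by two-colour TIRF microscopy of
labelled helicase on surface-tethered DNA. replitrace is an R toolkit for
exactly this class of experiment: it turns raw movies (or pre-extracted
intensity trajectories) into fluorophore-calibrated copy numbers and
kinetic parameters, and ships a synthetic-data generator that emulates
the experiments with known ground truth, so that every stage of the
analysis is testable without any raw movie.

The quantitative core, in the field's standard notation:

* **Photobleaching step counting.** A bleaching trace is segmented into
  piecewise-constant levels by binary segmentation under
  BIC(m) = n·log(RSS/n) + 2m·log n, with location refinement, a
  two-split lookahead for near-simultaneous bleaches, and pruning;
  downward steps count dyes.
* **Degree of labelling (DOL).** Steps per molecule fit by Poisson
  maximum likelihood; plain (λ̂ = mean) and zero-truncated
  (λ/(1−e^−λ) = k̄) estimators ship side by side because unlabelled
  molecules are invisible.
* **Stoichiometry.** copies = I₀ / (ν·λ), with ν the single-fluorophore
  intensity and λ the DOL; populations resolved by Gaussian-mixture EM,
  optionally constrained to integer-multiple means μ_m = m·μ₁ with
  σ_m = σ√m.
* **Colocalisation.** One-to-one matching within 2 px; chance
  coincidence C = (A_R / A_FOV) × n.
* **Kinetics.** Ensemble decays A·e^(−t/τ) with the competing-rates
  correction 1/τ_obs = 1/τ_off + 1/τ_bleach; FRAP recovery
  I(t) = a·e^(−t/τ_b) + I₀(1 − e^(−t/τ)); binding events by
  half-molecule thresholding with optional hysteresis, summarised as
  events·min⁻¹.

## Worked example

Calibrate the labelling, resolve loading stoichiometry, measure
stability, and count transient associations — all on simulated data with
known truth:

```r
library(replitrace)

# calibrate the labelling from surface-immobilised molecules
cal_data <- scenario_dol(seed = 7, n_molecules = 120)
steps <- lapply(cal_data$trajectories, detect_steps)
lambda_hat <- fit_poisson_dol(count_steps_per_molecule(steps))
calib <- labeling_calibration(200, 20, lambda_hat, n_molecules = 120)
print(calib)
#> <labeling_calibration> nu = 200 +/- 20 counts/fluorophore, lambda = 3.22 (n = 120)

# copy numbers of loaded helicases, and their population structure
loading <- scenario_loading(seed = 7, n_foci = 606)
copies <- sapply(loading$trajectories, function(tr)
  estimate_stoichiometry(tr, loading$calib)$copies)
fit <- fit_stoichiometry_mixture(copies, k = 3, mode = "constrained",
                                 scaled_sds = TRUE)
print(fit)
#> <mixture_fit> k = 3 (constrained, sqrt(m) sds), logLik -675.69, n = 603
#>   comp 1: mean 1.020, sd 0.341, weight 0.580
#>   comp 2: mean 2.041, sd 0.482, weight 0.276
#>   comp 3: mean 3.061, sd 0.590, weight 0.144

# how long does a loaded helicase stay? ensemble decay + bleach correction
stab <- scenario_lifetime(seed = 7, n_traj = 200)
ens <- ensemble_mean_trajectory(stab$trajectories)
decay <- fit_exponential_decay(ens$times, ens$intensities)
print(decay)
#> <decay_fit> A = 658, lifetime = 1396 +/- 4
cat(sprintf("bleach-corrected binding lifetime: %.1f min\n",
            bleach_corrected_lifetime(decay$lifetime / 60, 60)))
#> bleach-corrected binding lifetime: 38.0 min

# transient association at an assembled replisome
assoc <- scenario_association(seed = 7, n_traj = 40)
events <- lapply(assoc$trajectories, detect_binding_events,
                 calib = assoc$calib, exit_threshold_molecules = 0.25)
print(summarize_binding(events))
#>   group  n mean_frequency sem_frequency mean_fraction_bound single_series
#> 1   all 40         0.7475    0.02550452             0.37425         FALSE
```

Reading the output: the calibration found 3.22 dyes per hexamer from step
counting (the generator's visible-molecule truth is 3.32, an estimate not
a constant); the mixture resolved three populations at 1.02 / 2.04 / 3.06
copies with decreasing weights — one, two or three helicases per DNA; the
ensemble signal decays with a 1396 s composite lifetime which, corrected
for 60 min photobleaching, gives a ~38 min binding lifetime against a
generating truth of 34.4 min at this group size; and transient binders
were detected at 0.75 min⁻¹ against a generating event rate of
0.84 min⁻¹ (the half-molecule threshold inevitably misses some
single-dye binders — see the methods vignette).

Movie-based workflows start instead from `simulate_movie()` /
`read_movie_tiff()`, then `correct_movie()`, `detect_foci()`,
`link_trajectories()`, `colocalize()` and `make_kymograph()`; the staged
runner `run_pipeline()` and fixture writer `generate_fixtures()` wire
these together with provenance (seed, config hash) in every report.

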