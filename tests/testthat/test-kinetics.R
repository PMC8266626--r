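# Decay, FRAP and binding-event kinetics.

test_that("noiseless exponential samples are fit to high precision", {
  t <- seq(0, 50, by = 0.5)
  fit <- fit_exponential_decay(t, 100 * exp(-t / 10))
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$lifetime, 10, tolerance = 1e-6)
  with_off <- fit_exponential_decay(t, 100 * exp(-t / 10) + 7,
                                    fit_offset = TRUE)
  expect_equal(with_off$offset, 7, tolerance = 1e-4)
  expect_equal(with_off$lifetime, 10, tolerance = 1e-4)
})

test_that("constant data are rejected as undecaying", {
  expect_error(fit_exponential_decay(1:10, rep(5, 10)), "constant")
  expect_error(fit_exponential_decay(1:3, c(3, 2, 1)), "at least 5")
})

test_that("competing dissociation and bleaching compose as summed rates", {
  # reduced-n version of the ensemble-lifetime recovery (50 trajectories)
  sc <- scenario_lifetime(seed = 51L, n_traj = 50L)
  ens <- ensemble_mean_trajectory(sc$trajectories)
  fit <- fit_exponential_decay(ens$times, ens$intensities)
  comp <- composite_lifetime(34.4, 60) * 60
  expect_lt(abs(fit$lifetime - comp) / comp, 0.10)
})

test_that("bleach correction inverts the competing-rate law", {
  expect_equal(bleach_corrected_lifetime(10, Inf), 10)
  expect_equal(bleach_corrected_lifetime(5, 10), 10)
  expect_error(bleach_corrected_lifetime(10, 8), "exceed")
})

test_that("dose extrapolation scales inversely with time-averaged dose", {
  d <- list(irradiance = 100, duty = 1)
  expect_equal(extrapolate_bleach_lifetime(60, d, d), 60)
  half <- list(irradiance = 100, duty = 0.5)
  expect_equal(extrapolate_bleach_lifetime(60, d, half), 120)
  expect_error(extrapolate_bleach_lifetime(60, d,
                                           list(irradiance = 0, duty = 1)))
})

test_that("intermittent excitation extends simulated wall-clock bleaching 20-fold", {
  # 400 ms once every 8 s versus continuous: duty 0.05 vs 1
  mean_bleach_wall <- function(frame_interval, exposure, seed) {
    cfg <- sim_config(seed = seed, n_frames = 50L,
                      frame_interval = frame_interval, exposure = exposure,
                      read_noise_sd = 0, background_rate = 0,
                      bleach_tau = 30)
    tr <- simulate_trajectory(cfg,
      emitter_truth(n_hexamers = 800L, dye_counts = rep(4L, 800L)))
    mean(attr(tr, "truth")$dye_bleach_exposure_s) /
      (exposure / frame_interval)
  }
  cont <- mean_bleach_wall(0.4, 0.4, 61L)
  intermittent <- mean_bleach_wall(8, 0.4, 62L)
  expect_lt(abs(intermittent / cont - 20) / 20, 0.10)
})

test_that("noiseless FRAP curves return the generating parameters", {
  t <- seq(0, 900, by = 4)
  y <- frap_model(t, a = 2, tau_b = 300, I0 = 1, tau = 120)
  fit <- fit_frap_recovery(t, y)
  expect_equal(fit$a, 2, tolerance = 1e-4)
  expect_equal(fit$tau_b, 300, tolerance = 1e-4)
  expect_equal(fit$I0, 1, tolerance = 1e-4)
  expect_equal(fit$tau, 120, tolerance = 1e-4)
})

test_that("the FRAP model starts at the bleach amplitude and recovers monotonically", {
  t <- seq(0, 600, by = 2)
  y <- frap_model(t, a = 1.5, tau_b = 200, I0 = 2, tau = 90)
  fit <- fit_frap_recovery(t, y)
  expect_equal(frap_model(0, fit$a, fit$tau_b, fit$I0, fit$tau), fit$a)
  recovery <- fit$I0 * (1 - exp(-t / fit$tau))
  expect_true(all(diff(recovery) >= 0))
})

test_that("a zero bleach amplitude reduces FRAP to a saturating exponential", {
  t <- seq(0, 600, by = 4)
  y <- frap_model(t, a = 0, tau_b = 300, I0 = 1, tau = 120)
  expect_equal(y[1], 0)
  fit <- fit_frap_recovery(t, y)
  expect_lt(fit$a, 1e-6)
  expect_equal(fit$I0, 1, tolerance = 1e-4)
  expect_equal(fit$tau, 120, tolerance = 1e-3)
})

test_that("a trace below threshold has no events; square pulses are counted exactly", {
  calib <- labeling_calibration(100, 5, 2.52)
  quiet <- intensity_trajectory(0:599, rep(0, 600), period = 1)
  ev <- detect_binding_events(quiet, calib)
  expect_equal(ev$frequency, 0)
  expect_equal(ev$fraction_bound, 0)
  # 10-minute trace with 5 constructed pulses of 12 frames each
  sig <- rep(0, 600)
  for (s in c(50, 150, 250, 350, 450)) sig[s:(s + 11)] <- 300
  pulsed <- intensity_trajectory(0:599, sig, period = 1)
  ev5 <- detect_binding_events(pulsed, calib)
  expect_equal(nrow(ev5$events), 5)
  expect_equal(ev5$frequency, 0.5)
  expect_equal(ev5$fraction_bound, 60 / 600)
  expect_equal(ev5$threshold, 0.5 * 100 * 2.52)
})

test_that("noiseless telegraph episodes are counted exactly at min_duration 1", {
  cfg <- sim_config(seed = 63L, n_frames = 1200L, frame_interval = 0.5,
                    exposure = 0.5, read_noise_sd = 0, background_rate = 0,
                    bleach_tau = 1e12, photons_per_dye_per_frame = 100,
                    dol_lambda = 2.52)
  tg <- telegraph_params(on_rate = 2, mean_dwell = 20)
  tr <- simulate_trajectory(cfg,
    emitter_truth(kinetics_class = "transient-telegraph", dye_counts = 3L),
    telegraph = tg)
  truth <- attr(tr, "truth")
  # keep only episodes long enough to cover at least one frame midpoint
  mids <- tr$times + cfg$exposure / 2
  covered <- vapply(seq_len(nrow(truth$episodes)), function(i)
    any(mids >= truth$episodes[i, 1] & mids < truth$episodes[i, 2]),
    logical(1))
  calib <- labeling_calibration(100, 0, 2.52)
  ev <- detect_binding_events(tr, calib)
  expect_equal(nrow(ev$events), sum(covered))
})

test_that("hysteresis requires the exit below the entry threshold", {
  calib <- labeling_calibration(100, 5, 2.52)
  tr <- intensity_trajectory(0:9, rep(0, 10), period = 1)
  expect_error(detect_binding_events(tr, calib,
                                     exit_threshold_molecules = 0.6),
               "below")
})

test_that("binding summaries average frequencies with standard errors", {
  mk <- function(f, frac) structure(list(frequency = f,
                                         fraction_bound = frac),
                                    class = "binding_events")
  one <- summarize_binding(list(mk(1, 0.4)))
  expect_equal(one$mean_frequency, 1)
  expect_equal(one$sem_frequency, 0)
  expect_true(one$single_series)
  two <- summarize_binding(list(mk(0.5, 0.2), mk(1.5, 0.6)))
  expect_equal(two$mean_frequency, 1.0)
  expect_equal(two$sem_frequency, 0.5)
  expect_equal(two$mean_fraction_bound, 0.4)
  expect_error(summarize_binding(list()), "empty")
  grp <- summarize_binding(list(mk(1, 0.1), mk(2, 0.2), mk(5, 0.5)),
                           group = c("a", "a", "b"))
  expect_equal(grp$mean_frequency[grp$group == "a"], 1.5)
  expect_equal(grp$n[grp$group == "b"], 1)
})

test_that("the chase comparison distinguishes exchange from bleach-only loss", {
  # reduced-n version; the full Fig.4C-regime run is in the acceptance
  # suite
  ch <- scenario_chase(seed = 64L, n_chase = 15L, n_control = 120L,
                       duration_min = 12)
  cmp <- compare_lifetimes(ch$chase, ch$control, n_boot = 60L, seed = 9L)
  expect_gt(cmp$p_value, 0.05)
  chx <- scenario_chase(seed = 65L, n_chase = 15L, n_control = 120L,
                        duration_min = 12, exchange_rate = 0.3)
  cmpx <- compare_lifetimes(chx$chase, ch$control, n_boot = 60L, seed = 9L)
  expect_lt(cmpx$p_value, 0.05)
  expect_lt(cmpx$tau_a, cmp$tau_a)
})

test_that("dwell-time MLE handles censoring", {
  fit <- fit_lifetime_mle(c(2, 4, 6, 8), censored = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(fit$lifetime, 20 / 3)
  expect_error(fit_lifetime_mle(c(1, 2), censored = c(TRUE, TRUE)))
})

test_that("fit reports serialise to JSON", {
  t <- seq(0, 50, by = 1)
  fit <- fit_exponential_decay(t, 100 * exp(-t / 10))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model, "decay_fit")
  expect_equal(back$lifetime, 10, tolerance = 1e-6)
})
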