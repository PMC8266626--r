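# Pre-registered simulation scenarios mirroring the assays the pipeline is
# meant to analyse. Each returns in-memory objects with ground truth so a
# recovery test (or fixture write-out) can compare pipeline estimates
# against the generating parameters.

#' Degree-of-labelling calibration scenario
#'
#' Surface-immobilised single hexamers under continuous excitation
#' photobleach to completion; step counting on these traces calibrates the
#' labelling distribution. Dye counts follow the truncated-Poisson
#' labelling model; unlabelled hexamers are simulated too (they are
#' invisible, which is what makes the observed step counts
#' zero-truncated).
#'
#' @param seed Seed.
#' @param n_molecules Number of molecules (260 in the red-channel
#'   calibration this emulates).
#' @param lambda True mean dyes per hexamer.
#' @param snr Per-dye signal-to-noise ratio (step size over noise sd).
#' @param n_frames Trace length, frames.
#' @param bleach_frames Mean bleaching lifetime in frames of exposure.
#' @param photons Counts per dye per frame.
#' @return List with `trajectories` (list of [intensity_trajectory()]),
#'   `truth` (list of dye counts), and the generating `config`.
#' @export
scenario_dol <- function(seed = 1L, n_molecules = 260L, lambda = 3.5,
                         snr = 8, n_frames = 1000L, bleach_frames = 200,
                         photons = 200) {
  config <- sim_config(seed = seed, n_frames = n_frames,
                       frame_interval = 1, exposure = 1,
                       read_noise_sd = photons / snr,
                       background_rate = 0, offset = 0,
                       photons_per_dye_per_frame = photons,
                       dol_lambda = lambda, bleach_tau = bleach_frames,
                       dye_model = "tpois")
  with_seed(seed, {
    trajs <- vector("list", n_molecules)
    dye_counts <- integer(n_molecules)
    for (i in seq_len(n_molecules)) {
      truth <- emitter_truth(emitter_id = i,
                             kinetics_class = "immobile-surface")
      trajs[[i]] <- simulate_trajectory(config, truth, seed = NULL)
      dye_counts[i] <- sum(attr(trajs[[i]], "truth")$dye_counts)
    }
    list(trajectories = trajs, dye_counts = dye_counts, config = config)
  })
}

#' Helicase-loading stoichiometry scenario
#'
#' Foci carrying 1, 2 or 3 hexamers with decreasing occurrence, as on a
#' single-stranded loading site that accommodates up to three helicases.
#' Dyes per hexamer follow the binomial labelling model (independent
#' labelling of the six cysteine sites) — the underdispersed statistics
#' that give resolved integer populations. Foci with zero total dyes are
#' invisible and dropped, as in detection-conditioned data. Noise is
#' molecule-level: sd = (single-molecule intensity) / snr.
#'
#' @param seed Seed.
#' @param n_foci Number of simulated foci before the visibility cut.
#' @param weights Population weights for 1/2/3 hexamers.
#' @param lambda Mean dyes per hexamer.
#' @param snr Molecule-level signal-to-noise ratio.
#' @param photons Counts per dye per frame.
#' @param n_frames Frames per trace.
#' @return List with `trajectories`, `n_hexamers` (truth per visible
#'   focus), `calib` (the true [labeling_calibration()]), `config`.
#' @export
scenario_loading <- function(seed = 1L, n_foci = 606L,
                             weights = c(0.55, 0.30, 0.15),
                             lambda = 3.5, snr = 10, photons = 200,
                             n_frames = 10L) {
  with_seed(seed, {
    nh <- sample(seq_along(weights), n_foci, replace = TRUE, prob = weights)
    dyes <- stats::rbinom(n_foci, 6L * nh, lambda / 6)
    keep <- dyes >= 1
    nh <- nh[keep]; dyes <- dyes[keep]
    noise_sd <- lambda * photons / snr
    times <- seq_len(n_frames) - 1
    trajs <- lapply(seq_along(dyes), function(i) {
      intensity_trajectory(
        times,
        dyes[i] * photons + stats::rnorm(n_frames, 0, noise_sd),
        exposure = 1, period = 1, source_focus_id = i)
    })
    # true calibration: per-dye intensity and the full-population mean
    # dye count (the degree of labelling proper)
    calib <- labeling_calibration(photons, 0, lambda,
                                  n_molecules = length(dyes))
    list(trajectories = trajs, n_hexamers = nh, dye_counts = dyes,
         calib = calib)
  })
}

#' Loaded-helicase lifetime scenario
#'
#' Stable binders dissociating with an exponential lifetime while their
#' dyes photobleach, imaged intermittently (400 ms exposure every 8 s by
#' default). The ensemble mean intensity decays with the composite rate
#' `1/tau_off + 1/tau_bleach` (wall-clock); recovering both the composite
#' and the bleach-corrected dissociation lifetime is the object of the
#' fit.
#'
#' @param seed Seed.
#' @param n_traj Number of molecules.
#' @param tau_off_min True dissociation lifetime, minutes.
#' @param tau_bleach_min Wall-clock photobleaching lifetime, minutes.
#' @param frame_interval Seconds between frames.
#' @param exposure Excitation window per frame, seconds.
#' @param duration_min Observation span, minutes.
#' @param lambda,snr,photons Labelling and noise settings.
#' @return List with `trajectories`, `config`, and the generating
#'   parameters.
#' @export
scenario_lifetime <- function(seed = 1L, n_traj = 200L, tau_off_min = 34.4,
                              tau_bleach_min = 60, frame_interval = 8,
                              exposure = 0.4, duration_min = 120,
                              lambda = 3.5, snr = 10, photons = 200) {
  duty <- exposure / frame_interval
  n_frames <- ceiling(duration_min * 60 / frame_interval)
  config <- sim_config(seed = seed, n_frames = n_frames,
                       frame_interval = frame_interval, exposure = exposure,
                       read_noise_sd = lambda * photons / snr,
                       background_rate = 0, offset = 0,
                       photons_per_dye_per_frame = photons,
                       dol_lambda = lambda,
                       bleach_tau = tau_bleach_min * 60 * duty,
                       dye_model = "binomial")
  with_seed(seed, {
    trajs <- lapply(seq_len(n_traj), function(i) {
      unbind <- if (is.finite(tau_off_min))
        stats::rexp(1, 1 / (tau_off_min * 60)) else Inf
      truth <- emitter_truth(emitter_id = i, bind_time = 0,
                             unbind_time = max(unbind, 1e-6),
                             kinetics_class = "stable")
      simulate_trajectory(config, truth, seed = NULL)
    })
    list(trajectories = trajs, config = config,
         tau_off_min = tau_off_min, tau_bleach_min = tau_bleach_min)
  })
}

#' Chase exchange scenario
#'
#' The control arm images stable anchors whose only signal loss is
#' photobleaching (the bleach-only lifetime measurement); the chase arm
#' adds dissociation/exchange at `exchange_rate` per minute (zero for the
#' no-exchange hypothesis). Comparing the two fitted ensemble lifetimes
#' tests whether unlabelled helicase in solution displaces the anchored
#' one.
#'
#' @param seed Seed.
#' @param n_chase,n_control Molecules per arm.
#' @param tau_bleach_min Wall-clock bleaching lifetime, minutes.
#' @param exchange_rate Exchange rate in the chase arm, events/min
#'   (0 = stable anchor).
#' @param frame_interval,exposure Imaging schedule, seconds.
#' @param duration_min Observation span, minutes.
#' @param lambda,snr,photons Labelling and noise settings.
#' @return List with `chase` and `control` trajectory lists plus settings.
#' @export
scenario_chase <- function(seed = 1L, n_chase = 29L, n_control = 667L,
                           tau_bleach_min = 4.8, exchange_rate = 0,
                           frame_interval = 0.8, exposure = 0.4,
                           duration_min = 15, lambda = 3.5, snr = 10,
                           photons = 200) {
  tau_off_min <- if (exchange_rate > 0) 1 / exchange_rate else Inf
  control <- scenario_lifetime(seed, n_traj = n_control,
                               tau_off_min = Inf,
                               tau_bleach_min = tau_bleach_min,
                               frame_interval = frame_interval,
                               exposure = exposure,
                               duration_min = duration_min,
                               lambda = lambda, snr = snr,
                               photons = photons)
  chase <- scenario_lifetime(seed + 1L, n_traj = n_chase,
                             tau_off_min = tau_off_min,
                             tau_bleach_min = tau_bleach_min,
                             frame_interval = frame_interval,
                             exposure = exposure,
                             duration_min = duration_min,
                             lambda = lambda, snr = snr, photons = photons)
  list(chase = chase$trajectories, control = control$trajectories,
       tau_bleach_min = tau_bleach_min, exchange_rate = exchange_rate,
       frame_interval = frame_interval)
}

#' FRAP recovery scenario
#'
#' Noisy recovery curves drawn from the photobleaching-corrected FRAP
#' model `I(t) = a e^(-t/tau_b) + I0 (1 - e^(-t/tau))`, emulating summed
#' single-molecule recovery after a bleach pulse.
#'
#' @param seed Seed.
#' @param a,tau_b,I0,tau Generating parameters (see [frap_model()]).
#' @param t_max,dt Sampling grid, seconds.
#' @param noise_sd Gaussian noise sd in `I0` units.
#' @return List with `times`, `values`, and the generating parameters.
#' @export
scenario_frap <- function(seed = 1L, a = 2, tau_b = 300, I0 = 1,
                          tau = 120, t_max = 900, dt = 4,
                          noise_sd = 0.1) {
  with_seed(seed, {
    times <- seq(0, t_max, by = dt)
    clean <- frap_model(times, a, tau_b, I0, tau)
    values <- clean + stats::rnorm(length(times), 0, noise_sd * I0)
    list(times = times, values = values,
         truth = list(a = a, tau_b = tau_b, I0 = I0, tau = tau))
  })
}

#' Transient-association scenario
#'
#' Telegraph binding of labelled helicase from solution at a stationary
#' replisome: bound episodes start as an alternating renewal process and
#' each episode is carried by a fresh molecule with its own dye count
#' (zero-dye binders are dark and are not part of the measured rate, so
#' episode dye counts are drawn conditioned on >= 1). The generating
#' event rate is the closed-form renewal rate of
#' [telegraph_event_rate()].
#'
#' @param seed Seed.
#' @param event_rate Target overall event rate, events/min.
#' @param mean_dwell Mean bound dwell, seconds.
#' @param n_traj Number of trajectories.
#' @param duration_s Trajectory length, seconds.
#' @param frame_interval Seconds per frame.
#' @param lambda Mean dyes per molecule (blue-channel labelling).
#' @param snr Per-dye signal-to-noise ratio (single-fluorophore intensity
#'   over per-frame noise sd).
#' @param photons Counts per dye per frame.
#' @return List with `trajectories`, `true_rate` (= `event_rate`),
#'   `true_event_counts`, `calib`.
#' @export
scenario_association <- function(seed = 1L, event_rate = 0.84,
                                 mean_dwell = 30.7, n_traj = 123L,
                                 duration_s = 1200, frame_interval = 0.5,
                                 lambda = 2.52, snr = 8, photons = 200) {
  tg <- telegraph_params(telegraph_on_rate_for(event_rate, mean_dwell),
                         mean_dwell)
  wait_mean <- 60 / tg$on_rate
  noise_sd <- photons / snr
  with_seed(seed, {
    times <- seq(0, duration_s - frame_interval, by = frame_interval)
    trajs <- vector("list", n_traj)
    n_events <- integer(n_traj)
    for (i in seq_len(n_traj)) {
      t <- 0; starts <- numeric(0); ends <- numeric(0)
      while (t < duration_s) {
        t <- t + stats::rexp(1, 1 / wait_mean)
        if (t >= duration_s) break
        d <- stats::rexp(1, 1 / mean_dwell)
        starts <- c(starts, t); ends <- c(ends, min(t + d, duration_s))
        t <- t + d
      }
      dyes <- draw_dye_counts(length(starts), lambda, model = "tpois")
      while (any(dyes == 0)) dyes[dyes == 0] <-
        draw_dye_counts(sum(dyes == 0), lambda, model = "tpois")
      signal <- rep(0, length(times))
      for (e in seq_along(starts)) {
        inside <- times >= starts[e] & times < ends[e]
        signal[inside] <- signal[inside] + dyes[e] * photons
      }
      trajs[[i]] <- intensity_trajectory(
        times, signal + stats::rnorm(length(times), 0, noise_sd),
        exposure = frame_interval, period = frame_interval,
        source_focus_id = i)
      n_events[i] <- length(starts)
    }
    list(trajectories = trajs, true_rate = event_rate,
         true_event_counts = n_events,
         calib = labeling_calibration(photons, 0, lambda,
                                      n_molecules = n_traj))
  })
}
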