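# Lifetime, FRAP and binding-event kinetics.

#' Fit a single-exponential decay
#'
#' Nonlinear least squares of `A * exp(-t / tau)` (plus a constant offset
#' when `fit_offset`). Initial guesses: `A` from the first value, `tau`
#' from the time at which the data fall to `A / e` (linear interpolation).
#'
#' @param times Times in seconds (or any unit; `lifetime` inherits it).
#' @param values Decaying signal (counts or molecules).
#' @param fit_offset Include a constant offset term.
#' @return An object of class `decay_fit`: `amplitude`, `lifetime`,
#'   `offset`, `se` (named vector of standard errors), `cov`, `fitted`,
#'   `residuals`, `times`.
#' @export
fit_exponential_decay <- function(times, values, fit_offset = FALSE) {
  if (length(times) < 5) stopf("need at least 5 points")
  if (length(times) != length(values)) stopf("length mismatch")
  if (stats::sd(values) == 0) stopf("constant data: no decay to fit")
  A0 <- values[1]
  if (A0 <= 0) A0 <- max(values)
  target <- A0 / exp(1)
  below <- which(values <= target)
  tau0 <- if (length(below)) {
    i <- below[1]
    if (i == 1) times[1] + diff(range(times)) / 10
    else times[i - 1] + (times[i] - times[i - 1]) *
      (values[i - 1] - target) / (values[i - 1] - values[i])
  } else diff(range(times))
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(times)) / 3
  df <- data.frame(t = times, y = values)
  fit <- if (fit_offset) {
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + c0, data = df,
                      start = list(A = A0, tau = tau0, c0 = min(values)),
                      lower = c(A = 0, tau = 1e-12, c0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(y ~ A * exp(-t / tau), data = df,
                      start = list(A = A0, tau = tau0),
                      lower = c(A = 0, tau = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  if (!fit$convInfo$isConv)
    stopf("exponential fit did not converge: %s", fit$convInfo$stopMessage)
  cf <- stats::coef(fit)
  sm <- summary(fit)
  structure(list(amplitude = unname(cf["A"]),
                 lifetime = unname(cf["tau"]),
                 offset = if (fit_offset) unname(cf["c0"]) else 0,
                 se = sm$coefficients[, "Std. Error"],
                 cov = stats::vcov(fit),
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 times = times),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> A = %.4g, lifetime = %.4g +/- %.2g%s\n",
              x$amplitude, x$lifetime, x$se["tau"],
              if (x$offset != 0) sprintf(", offset = %.3g", x$offset) else ""))
  invisible(x)
}

#' Ensemble mean of aligned trajectories
#'
#' Averages intensity over trajectories sharing a common frame grid — the
#' ensemble decay whose single-exponential fit gives the mean binding (or
#' bleaching) lifetime.
#'
#' @param trajs List of [intensity_trajectory()] objects on one time grid.
#' @return An [intensity_trajectory()] of the per-frame means.
#' @export
ensemble_mean_trajectory <- function(trajs) {
  if (!length(trajs)) stopf("no trajectories")
  times <- trajs[[1]]$times
  mat <- vapply(trajs, function(tr) {
    if (length(tr$times) != length(times))
      stopf("trajectories are not on a common frame grid")
    tr$intensities
  }, numeric(length(times)))
  intensity_trajectory(times, rowMeans(mat),
                       exposure = trajs[[1]]$exposure,
                       period = trajs[[1]]$period)
}

#' Exponential lifetime from pooled dwell times
#'
#' Maximum-likelihood mean of an exponential dwell distribution with
#' right-censoring: `sum(all dwells) / number of complete dwells`.
#' Alternative to ensemble-curve fitting when individual unbinding times
#' are resolved.
#'
#' @param dwells Observed dwell times.
#' @param censored Logical; `TRUE` where the dwell was cut short by the end
#'   of observation.
#' @return List with `lifetime` and `se`.
#' @export
fit_lifetime_mle <- function(dwells, censored = rep(FALSE, length(dwells))) {
  n_events <- sum(!censored)
  if (n_events == 0) stopf("no uncensored dwells")
  tau <- sum(dwells) / n_events
  list(lifetime = tau, se = tau / sqrt(n_events))
}

#' Compare two ensemble lifetimes with bootstrap errors
#'
#' Fits a single-exponential decay to the ensemble mean of each trajectory
#' group and tests whether the two lifetimes differ. Standard errors come
#' from a molecule-level bootstrap (resampling trajectories with
#' replacement and refitting), because the residuals of an ensemble-mean
#' fit are strongly correlated across frames — per-molecule bleaching and
#' dissociation are random paths — and the asymptotic errors of the curve
#' fit alone understate the uncertainty by an order of magnitude for small
#' groups. The z statistic compares the lifetime difference against the
#' combined bootstrap errors.
#'
#' This is the chase-assay logic: a chase arm statistically
#' indistinguishable from the bleach-only control means signal loss is
#' explained by photobleaching alone (no exchange).
#'
#' @param trajs_a,trajs_b Lists of [intensity_trajectory()] on common
#'   grids.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @param fit_offset Passed to [fit_exponential_decay()].
#' @return List with `tau_a`, `tau_b`, `se_a`, `se_b` (bootstrap), `z`,
#'   `p_value` (two-sided normal).
#' @export
compare_lifetimes <- function(trajs_a, trajs_b, n_boot = 200L, seed = 1L,
                              fit_offset = FALSE) {
  fit_group <- function(mat, times) {
    fit_exponential_decay(times, rowMeans(mat), fit_offset = fit_offset)$lifetime
  }
  boot_se <- function(mat, times) {
    n <- ncol(mat)
    taus <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_group(mat[, idx, drop = FALSE], times),
               error = function(e) NA_real_)
    }, numeric(1))
    stats::sd(taus, na.rm = TRUE)
  }
  times_a <- trajs_a[[1]]$times
  times_b <- trajs_b[[1]]$times
  mat_a <- vapply(trajs_a, function(tr) tr$intensities,
                  numeric(length(times_a)))
  mat_b <- vapply(trajs_b, function(tr) tr$intensities,
                  numeric(length(times_b)))
  tau_a <- fit_group(mat_a, times_a)
  tau_b <- fit_group(mat_b, times_b)
  with_seed(seed, {
    se_a <- boot_se(mat_a, times_a)
    se_b <- boot_se(mat_b, times_b)
  })
  z <- (tau_a - tau_b) / sqrt(se_a^2 + se_b^2)
  list(tau_a = tau_a, tau_b = tau_b, se_a = se_a, se_b = se_b,
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Correct an observed lifetime for photobleaching
#'
#' Dissociation and photobleaching compete as independent exponential
#' processes, so observed rates add: `1 / tau_obs = 1 / tau_off + 1 /
#' tau_bleach`. Returns the bleaching-corrected dissociation lifetime
#' `1 / (1 / tau_obs - 1 / tau_bleach)`.
#'
#' @param tau_obs Observed (composite) lifetime.
#' @param tau_bleach Photobleaching lifetime in the same units; must exceed
#'   `tau_obs`.
#' @return Corrected lifetime.
#' @export
bleach_corrected_lifetime <- function(tau_obs, tau_bleach) {
  assert_scalar_num(tau_obs, "tau_obs", 0, strict_lower = TRUE)
  if (tau_bleach <= tau_obs)
    stopf("tau_bleach (%g) must exceed tau_obs (%g): the observed decay cannot be slower than bleaching alone",
          tau_bleach, tau_obs)
  1 / (1 / tau_obs - 1 / tau_bleach)
}

#' Extrapolate a photobleaching lifetime to another excitation dose
#'
#' Photobleaching probability is proportional to absorbed dose, so the
#' bleaching lifetime scales inversely with the time-averaged dose
#' (irradiance x duty cycle): `tau_target = tau_ref * dose_ref /
#' dose_target`. This is how a lifetime measured under continuous
#' excitation is converted to an intermittent schedule such as 400 ms of
#' excitation every 8 s.
#'
#' @param reference_tau Measured bleaching lifetime, s.
#' @param reference_dose,target_dose Lists with `irradiance` (any common
#'   unit) and `duty` (fraction of wall time excited).
#' @return Extrapolated wall-clock bleaching lifetime, s.
#' @export
extrapolate_bleach_lifetime <- function(reference_tau, reference_dose,
                                        target_dose) {
  d_ref <- reference_dose$irradiance * reference_dose$duty
  d_tgt <- target_dose$irradiance * target_dose$duty
  if (d_ref <= 0 || d_tgt <= 0) stopf("doses must be positive")
  reference_tau * d_ref / d_tgt
}

#' Fit a FRAP recovery curve with photobleaching correction
#'
#' Nonlinear least squares of
#' `I(t) = a * exp(-t / tau_b) + I0 * (1 - exp(-t / tau))`,
#' where `a` is the photobleaching amplitude, `tau_b` the photobleaching
#' time, `I0` the steady-state copy number at the fork and `tau` the
#' characteristic exchange time. All parameters are bounded positive.
#' Initial guesses: `a` from the first value, `I0` from the last, both
#' time constants at a third of the span.
#'
#' @param times Seconds since the bleach pulse (>= 8 points).
#' @param values Copy number (or intensity) over time.
#' @param start Optional named list overriding the initial guesses.
#' @return An object of class `frap_fit`: `a`, `tau_b`, `I0`, `tau`, `se`,
#'   `cov`, `fitted`, `residuals`, `times`.
#' @export
fit_frap_recovery <- function(times, values, start = NULL) {
  if (length(times) < 8) stopf("need at least 8 points")
  if (length(times) != length(values)) stopf("length mismatch")
  span <- diff(range(times))
  df <- data.frame(t = times, y = values)
  # multi-start over distinct time-constant pairs: equal tau and tau_b
  # make the two model terms nearly collinear and the Jacobian singular
  # keep the starting amplitude off zero: a = 0 zeroes the tau_b Jacobian
  # column and the solver cannot leave a singular start
  a0 <- max(values[1], 0.05 * max(abs(values)), 1e-6)
  I00 <- max(values[length(values)], 1e-6)
  starts <- list()
  for (fb in c(0.5, 1, 0.25)) for (fr in c(1 / 6, 1 / 3, 1 / 12)) {
    if (abs(fb - fr) < 1e-9) next
    starts[[length(starts) + 1]] <-
      list(a = a0, tau_b = fb * span, I0 = I00, tau = fr * span)
  }
  if (!is.null(start)) {
    s1 <- starts[[1]]; s1[names(start)] <- start
    starts <- c(list(s1), starts)
  }
  fit <- NULL
  fallback <- NULL
  for (s in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-t / tau_b) + I0 * (1 - exp(-t / tau)), data = df,
        start = s,
        lower = c(a = 0, tau_b = 1e-9, I0 = 0, tau = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(cand)) next
    rss <- sum(stats::resid(cand)^2)
    if (cand$convInfo$isConv) {
      if (is.null(fit) || rss < sum(stats::resid(fit)^2)) fit <- cand
    } else if (is.null(fallback) ||
               rss < sum(stats::resid(fallback)^2)) {
      fallback <- cand
    }
  }
  if (is.null(fit) && !is.null(fallback)) {
    # parameters pinned at a bound (e.g. a = 0) end iteration without the
    # formal convergence flag; accept only an essentially perfect fit
    if (sum(stats::resid(fallback)^2) <= 1e-16 * sum(values^2) + 1e-12)
      fit <- fallback
  }
  if (is.null(fit)) stopf("FRAP fit did not converge from any start")
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), tau_b = unname(cf["tau_b"]),
                 I0 = unname(cf["I0"]), tau = unname(cf["tau"]),
                 se = summary(fit)$coefficients[, "Std. Error"],
                 cov = stats::vcov(fit),
                 fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 times = times),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> a = %.3g, tau_b = %.4g s, I0 = %.3g, tau = %.4g s\n",
              x$a, x$tau_b, x$I0, x$tau))
  invisible(x)
}

#' Evaluate the FRAP model
#'
#' @param t Times, s.
#' @param a,tau_b,I0,tau Model parameters (see [fit_frap_recovery()]).
#' @return Model intensity at `t`.
#' @export
frap_model <- function(t, a, tau_b, I0, tau) {
  a * exp(-t / tau_b) + I0 * (1 - exp(-t / tau))
}

#' Detect binding events by intensity thresholding
#'
#' The threshold is set to `threshold_molecules` molecules — half a
#' molecule by default — converted to counts through the calibration
#' (`threshold_molecules * single-fluorophore intensity * dol_lambda`).
#' An event is a maximal run of at least `min_duration` consecutive frames
#' above threshold. The binding frequency is events per minute of
#' trajectory duration; the bound fraction is the fraction of frames above
#' threshold.
#'
#' With `exit_threshold_molecules` set below the entry threshold, the
#' detector uses hysteresis: an event starts when the intensity exceeds
#' the entry threshold and ends only when it falls below the exit
#' threshold, which prevents noise around the entry level from splitting
#' one binding event into several.
#'
#' @param traj An [intensity_trajectory()].
#' @param calib A [labeling_calibration()] for the relevant channel.
#' @param threshold_molecules Threshold in molecule units.
#' @param min_duration Minimum event length in frames.
#' @param exit_threshold_molecules Optional lower exit threshold in
#'   molecule units (hysteresis); `NULL` for a single threshold.
#' @return An object of class `binding_events`: `threshold` (counts),
#'   `events` (data frame `t_start`, `t_end`, `n_frames`), `frequency`
#'   (events/min), `fraction_bound`, `duration` (s), `n_frames`.
#' @export
detect_binding_events <- function(traj, calib, threshold_molecules = 0.5,
                                  min_duration = 1L,
                                  exit_threshold_molecules = NULL) {
  per_molecule <- calib$single_fluor_intensity_mean * calib$dol_lambda
  threshold <- threshold_molecules * per_molecule
  n <- length(traj$times)
  if (n == 0) {
    return(structure(list(threshold = threshold,
                          events = data.frame(t_start = numeric(0),
                                              t_end = numeric(0),
                                              n_frames = integer(0)),
                          frequency = 0, fraction_bound = 0,
                          duration = 0, n_frames = 0L),
                     class = "binding_events"))
  }
  dt <- if (!is.na(traj$period)) traj$period
        else if (n > 1) stats::median(diff(traj$times)) else 1
  above <- traj$intensities > threshold
  if (!is.null(exit_threshold_molecules)) {
    exit_thr <- exit_threshold_molecules * per_molecule
    if (exit_thr >= threshold)
      stopf("exit threshold must lie below the entry threshold")
    inside <- FALSE
    state <- logical(n)
    for (i in seq_len(n)) {
      if (!inside && traj$intensities[i] > threshold) inside <- TRUE
      else if (inside && traj$intensities[i] < exit_thr) inside <- FALSE
      state[i] <- inside
    }
    above <- state
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_duration
  events <- data.frame(
    t_start = traj$times[starts[keep]],
    t_end = traj$times[ends[keep]] + dt,
    n_frames = r$lengths[keep])
  duration <- n * dt
  structure(list(threshold = threshold, events = events,
                 frequency = nrow(events) / (duration / 60),
                 fraction_bound = mean(above),
                 duration = duration, n_frames = as.integer(n)),
            class = "binding_events")
}

#' @export
print.binding_events <- function(x, ...) {
  cat(sprintf("<binding_events> %d events in %.1f s: %.3g per min, bound %.1f%% of the time\n",
              nrow(x$events), x$duration, x$frequency,
              100 * x$fraction_bound))
  invisible(x)
}

#' Summarise binding-event series across trajectories
#'
#' Mean and standard error of the binding frequency and the mean bound
#' fraction, per group.
#'
#' @param series_list List of [detect_binding_events()] results.
#' @param group Optional grouping vector (one entry per series).
#' @return Data frame with columns `group`, `n`, `mean_frequency`,
#'   `sem_frequency` (0 with `single_series = TRUE` flag when n = 1),
#'   `mean_fraction_bound`.
#' @export
summarize_binding <- function(series_list, group = NULL) {
  if (!length(series_list)) stopf("empty group")
  if (is.null(group)) group <- rep("all", length(series_list))
  freq <- vapply(series_list, function(s) s$frequency, numeric(1))
  frac <- vapply(series_list, function(s) s$fraction_bound, numeric(1))
  out <- do.call(rbind, lapply(unique(group), function(g) {
    i <- group == g
    n <- sum(i)
    data.frame(group = g, n = n,
               mean_frequency = mean(freq[i]),
               sem_frequency = if (n > 1) stats::sd(freq[i]) / sqrt(n) else 0,
               mean_fraction_bound = mean(frac[i]),
               single_series = n == 1)
  }))
  rownames(out) <- NULL
  out
}

#' Write a kinetic fit report as JSON
#'
#' @param fit A `decay_fit`, `frap_fit` or `binding_events` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- unclass(fit)
  out$cov <- NULL
  out$model <- class(fit)[1]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
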