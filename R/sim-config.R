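#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator: camera geometry and
#' noise, point-spread function, fluorophore photophysics, labelling
#' statistics and the excitation schedule. Defaults emulate a back-thinned
#' EMCCD imaging surface-immobilised hexameric helicases through a TIRF
#' objective; intermittent excitation ("400 ms once every 8 s" style
#' schedules) is expressed through `exposure` and `frame_interval`.
#'
#' @param seed Integer seed controlling every random draw made with this
#'   configuration. Identical seed + config gives bit-identical output.
#' @param field_shape Integer vector `c(height, width)` of the field of view
#'   in pixels.
#' @param pixel_size Pixel size in nm (metadata only; no optics are derived
#'   from it).
#' @param frame_interval Wall-clock time between frame starts, in seconds.
#' @param exposure Excitation/integration window per frame, in seconds.
#'   Must not exceed `frame_interval`.
#' @param n_frames Number of frames.
#' @param offset Camera electronic offset, in counts.
#' @param read_noise_sd Gaussian read-noise standard deviation, in counts.
#'   For trajectory-level simulation this is the total effective noise after
#'   background subtraction.
#' @param background_rate Background photon rate, counts/pixel/frame.
#' @param psf_sigma Isotropic Gaussian PSF width, in pixels.
#' @param photons_per_dye_per_frame Detected counts contributed by one
#'   active fluorophore in one frame.
#' @param dol_lambda Mean number of dyes per hexamer (degree of labelling).
#' @param max_dyes Maximum dyes per hexamer (six labelling sites).
#' @param bleach_tau Mean photobleaching lifetime of a single dye, in
#'   seconds of *cumulative exposure* (the bleaching clock only advances
#'   while the laser is on, which is what makes intermittent excitation
#'   extend wall-clock fluorophore lifetimes).
#' @param dye_model Distribution of dye counts per hexamer:
#'   `"tpois"` for Poisson(`dol_lambda`) truncated to `[0, max_dyes]`, or
#'   `"binomial"` for Binomial(`max_dyes`, `dol_lambda / max_dyes`)
#'   (independent labelling of each cysteine site; underdispersed relative
#'   to Poisson).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       field_shape = c(64L, 64L),
                       pixel_size = 160,
                       frame_interval = 1,
                       exposure = 1,
                       n_frames = 100L,
                       offset = 100,
                       read_noise_sd = 2,
                       background_rate = 5,
                       psf_sigma = 1.3,
                       photons_per_dye_per_frame = 200,
                       dol_lambda = 3.5,
                       max_dyes = 6L,
                       bleach_tau = 100,
                       dye_model = c("tpois", "binomial")) {
  dye_model <- match.arg(dye_model)
  assert_scalar_num(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  assert_scalar_num(frame_interval, "frame_interval", 0, strict_lower = TRUE)
  assert_scalar_num(exposure, "exposure", 0, strict_lower = TRUE)
  if (frame_interval < exposure)
    stopf("`frame_interval` (%g s) must be >= `exposure` (%g s)",
          frame_interval, exposure)
  assert_scalar_num(n_frames, "n_frames", 1)
  assert_scalar_num(offset, "offset", 0)
  assert_scalar_num(read_noise_sd, "read_noise_sd", 0)
  assert_scalar_num(background_rate, "background_rate", 0)
  assert_scalar_num(psf_sigma, "psf_sigma", 0, strict_lower = TRUE)
  assert_scalar_num(photons_per_dye_per_frame, "photons_per_dye_per_frame",
                    0, strict_lower = TRUE)
  assert_scalar_num(dol_lambda, "dol_lambda", 0, strict_lower = TRUE)
  assert_scalar_num(max_dyes, "max_dyes", 1)
  assert_scalar_num(bleach_tau, "bleach_tau", 0, strict_lower = TRUE)
  if (length(field_shape) != 2 || any(field_shape < 1))
    stopf("`field_shape` must be c(height, width) with positive entries")
  structure(list(
    seed = as.integer(seed),
    field_shape = as.integer(field_shape),
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    exposure = exposure,
    n_frames = as.integer(n_frames),
    offset = offset,
    read_noise_sd = read_noise_sd,
    background_rate = background_rate,
    psf_sigma = psf_sigma,
    photons_per_dye_per_frame = photons_per_dye_per_frame,
    dol_lambda = dol_lambda,
    max_dyes = as.integer(max_dyes),
    bleach_tau = bleach_tau,
    duty_cycle = exposure / frame_interval,
    dye_model = dye_model
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  field %d x %d px, %d frames, %g s interval (%g s exposure, duty %.2f)\n",
              x$field_shape[1], x$field_shape[2], x$n_frames,
              x$frame_interval, x$exposure, x$duty_cycle))
  cat(sprintf("  offset %g, read noise %g, background %g counts/px/frame\n",
              x$offset, x$read_noise_sd, x$background_rate))
  cat(sprintf("  PSF sigma %g px, %g counts/dye/frame, DOL %s(%g, max %d), bleach tau %g s exposure\n",
              x$psf_sigma, x$photons_per_dye_per_frame, x$dye_model,
              x$dol_lambda, x$max_dyes, x$bleach_tau))
  invisible(x)
}

#' Kinetic parameters of a transiently binding species
#'
#' Two-state telegraph process: from the unbound state, binding occurs after
#' an exponential waiting time with rate `on_rate` (events per minute);
#' each bound episode lasts an exponential dwell with mean `mean_dwell`
#' seconds. The long-run event (upward-crossing) rate of this alternating
#' renewal process is `1 / (60 / on_rate + mean_dwell)` per second; see
#' [telegraph_event_rate()].
#'
#' @param on_rate Binding rate from the unbound state, events/min.
#' @param mean_dwell Mean bound-state dwell time, seconds.
#' @return An object of class `telegraph_params`.
#' @export
telegraph_params <- function(on_rate, mean_dwell) {
  assert_scalar_num(on_rate, "on_rate", 0, strict_lower = TRUE)
  assert_scalar_num(mean_dwell, "mean_dwell", 0, strict_lower = TRUE)
  structure(list(on_rate = on_rate, mean_dwell = mean_dwell),
            class = "telegraph_params")
}

#' True event rate of a telegraph process
#'
#' Closed-form long-run rate of bound-episode starts for an alternating
#' renewal process with exponential unbound waits (rate `on_rate` per
#' minute) and exponential bound dwells (`mean_dwell` seconds). Used as the
#' independent truth in recovery tests.
#'
#' @param telegraph A [telegraph_params()] object.
#' @return Event rate in events per minute.
#' @export
telegraph_event_rate <- function(telegraph) {
  60 / (60 / telegraph$on_rate + telegraph$mean_dwell)
}

#' On-rate that yields a target overall event rate
#'
#' Inverts [telegraph_event_rate()]: given the observable events-per-minute
#' rate and the mean bound dwell, returns the unbound-state `on_rate`
#' required by [telegraph_params()].
#'
#' @param event_rate Target overall event rate, events/min.
#' @param mean_dwell Mean bound dwell, seconds.
#' @return On-rate in events/min.
#' @export
telegraph_on_rate_for <- function(event_rate, mean_dwell) {
  cycle <- 60 / event_rate           # seconds per event
  wait <- cycle - mean_dwell
  if (wait <= 0)
    stopf("event rate %g/min is unreachable with mean dwell %g s",
          event_rate, mean_dwell)
  60 / wait
}

#' Ground-truth description of one emitter
#'
#' The truth record carried alongside every simulated trajectory or movie;
#' parameter-recovery tests compare pipeline output against it.
#'
#' @param emitter_id Integer identifier.
#' @param x,y Position in pixels (sub-pixel, 0-based, pixel centre at
#'   integer coordinates). For moving emitters, give the position at time 0
#'   and a `vx`/`vy` drift in px/s.
#' @param n_hexamers Number of hexamers in the focus.
#' @param dye_counts Integer vector, dyes per hexamer (length
#'   `n_hexamers`); `NULL` to draw from the configured labelling model.
#' @param bind_time,unbind_time Bound interval in seconds; `unbind_time =
#'   Inf` for emitters that never dissociate.
#' @param kinetics_class One of `"stable"`, `"transient-telegraph"`,
#'   `"immobile-surface"`.
#' @param vx,vy Drift velocity in px/s (replication-fork motion).
#' @return An object of class `emitter_truth`.
#' @export
emitter_truth <- function(emitter_id = 1L, x = 0, y = 0,
                          n_hexamers = 1L, dye_counts = NULL,
                          bind_time = 0, unbind_time = Inf,
                          kinetics_class = c("stable", "transient-telegraph",
                                             "immobile-surface"),
                          vx = 0, vy = 0) {
  kinetics_class <- match.arg(kinetics_class)
  if (bind_time >= unbind_time)
    stopf("`bind_time` must be < `unbind_time`")
  if (!is.null(dye_counts)) {
    if (length(dye_counts) != n_hexamers)
      stopf("`dye_counts` must have one entry per hexamer")
    if (any(dye_counts < 0))
      stopf("`dye_counts` must be non-negative")
  }
  structure(list(
    emitter_id = as.integer(emitter_id), x = x, y = y,
    n_hexamers = as.integer(n_hexamers),
    dye_counts = if (is.null(dye_counts)) NULL else as.integer(dye_counts),
    bind_time = bind_time, unbind_time = unbind_time,
    kinetics_class = kinetics_class, vx = vx, vy = vy
  ), class = "emitter_truth")
}

#' Draw dye counts per hexamer under the configured labelling model
#'
#' `"tpois"` renormalises Poisson(`lambda`) on `0..max_dyes`; `"binomial"`
#' labels each of the `max_dyes` sites independently with probability
#' `lambda / max_dyes`.
#'
#' @param n Number of hexamers to draw.
#' @param lambda Mean dyes per hexamer.
#' @param max_dyes Sites per hexamer.
#' @param model `"tpois"` or `"binomial"`.
#' @return Integer vector of dye counts.
#' @export
draw_dye_counts <- function(n, lambda, max_dyes = 6L,
                            model = c("tpois", "binomial")) {
  model <- match.arg(model)
  if (model == "binomial") {
    p <- lambda / max_dyes
    if (p > 1) stopf("binomial dye model needs lambda <= max_dyes")
    return(stats::rbinom(n, max_dyes, p))
  }
  p <- stats::dpois(0:max_dyes, lambda)
  sample(0:max_dyes, n, replace = TRUE, prob = p / sum(p))
}

#' Moments of the truncated Poisson labelling distribution
#'
#' Mean of Poisson(`lambda`) truncated to `0..max_dyes`, optionally
#' conditioned on at least one dye (only labelled molecules are visible).
#'
#' @param lambda Poisson mean before truncation.
#' @param max_dyes Upper truncation bound.
#' @param exclude_zero Condition on >= 1 dye.
#' @return The truncated mean.
#' @export
tpois_mean <- function(lambda, max_dyes = 6L, exclude_zero = FALSE) {
  k <- 0:max_dyes
  p <- stats::dpois(k, lambda)
  if (exclude_zero) sum(k * p) / sum(p[-1]) else sum(k * p) / sum(p)
}
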