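# Synthetic-data generator: intensity trajectories, movies and fork
# scenarios with ground-truth sidecars. All randomness is governed by
# config$seed so identical inputs give bit-identical outputs.

# Bound/unbound indicator sampled at the midpoints of the exposure windows,
# plus the true bound episodes. For telegraph emitters the process starts
# unbound at t = 0 and alternates exponential waits.
simulate_binding <- function(truth, telegraph, times, exposure, t_end) {
  mids <- times + exposure / 2
  if (truth$kinetics_class == "transient-telegraph") {
    if (is.null(telegraph))
      stopf("telegraph emitter requires `telegraph` parameters")
    wait_mean <- 60 / telegraph$on_rate
    t <- 0
    starts <- numeric(0); ends <- numeric(0)
    while (t < t_end) {
      t <- t + stats::rexp(1, 1 / wait_mean)
      if (t >= t_end) break
      d <- stats::rexp(1, 1 / telegraph$mean_dwell)
      starts <- c(starts, t); ends <- c(ends, min(t + d, t_end))
      t <- t + d
    }
    bound <- rep(FALSE, length(mids))
    for (i in seq_along(starts))
      bound <- bound | (mids >= starts[i] & mids < ends[i])
    list(bound = bound, episodes = cbind(t_start = starts, t_end = ends))
  } else {
    bound <- mids >= truth$bind_time & mids < truth$unbind_time
    list(bound = bound,
         episodes = cbind(t_start = truth$bind_time,
                          t_end = min(truth$unbind_time, t_end)))
  }
}

# Per-dye bleach times in cumulative-exposure seconds, and the fraction of
# each frame's exposure window each dye survives (0..1 per dye x frame).
simulate_bleaching <- function(n_dyes, bleach_tau, n_frames, exposure) {
  bleach_exp <- stats::rexp(n_dyes, 1 / bleach_tau)
  starts <- (seq_len(n_frames) - 1) * exposure
  frac <- matrix(0, nrow = n_dyes, ncol = n_frames)
  for (d in seq_len(n_dyes)) {
    f <- (bleach_exp[d] - starts) / exposure
    frac[d, ] <- pmin(pmax(f, 0), 1)
  }
  list(bleach_exposure_s = bleach_exp, survive_frac = frac)
}

#' Simulate one intensity trajectory
#'
#' Generates the background-subtracted intensity trace of a single focus:
#' the number of bound, unbleached dyes times the per-dye brightness, plus
#' Gaussian effective noise of sd `config$read_noise_sd`. Per-dye
#' photobleaching is exponential in cumulative *exposure* time, so halving
#' the duty cycle doubles the wall-clock fluorophore lifetime. Shot noise is
#' a movie-level effect (see [simulate_movie()]); for extracted
#' trajectories `read_noise_sd` stands for the total effective noise after
#' background subtraction, and setting it to zero with zero background
#' yields a noise-free trace.
#'
#' @param config A [sim_config()].
#' @param truth An [emitter_truth()]; `dye_counts` are drawn from the
#'   configured labelling model when absent.
#' @param telegraph [telegraph_params()], required when
#'   `truth$kinetics_class == "transient-telegraph"`.
#' @param seed Seed for this draw; defaults to `config$seed`. Use `NULL`
#'   to consume the caller's RNG stream (for batch simulation under one
#'   outer seed).
#' @return An [intensity_trajectory()] with attribute `"truth"`: the echoed
#'   [emitter_truth()] augmented with the drawn `dye_counts`,
#'   `dye_bleach_exposure_s` and (for telegraph emitters) the true bound
#'   `episodes` matrix.
#' @export
simulate_trajectory <- function(config, truth, telegraph = NULL,
                                seed = config$seed) {
  if (truth$unbind_time < Inf && truth$unbind_time >
        config$n_frames * config$frame_interval * 10)
    stopf("truth `unbind_time` lies far outside the simulated duration")
  with_seed(seed, {
    n <- config$n_frames
    times <- (seq_len(n) - 1) * config$frame_interval
    dye_counts <- truth$dye_counts %||%
      draw_dye_counts(truth$n_hexamers, config$dol_lambda, config$max_dyes,
                      config$dye_model)
    n_dyes <- sum(dye_counts)
    bl <- simulate_bleaching(n_dyes, config$bleach_tau, n, config$exposure)
    bind <- simulate_binding(truth, telegraph, times, config$exposure,
                             t_end = n * config$frame_interval)
    active <- if (n_dyes > 0) colSums(bl$survive_frac) else rep(0, n)
    signal <- active * config$photons_per_dye_per_frame * as.numeric(bind$bound)
    noise <- if (config$read_noise_sd > 0)
      stats::rnorm(n, 0, config$read_noise_sd) else 0
    truth$dye_counts <- dye_counts
    truth$dye_bleach_exposure_s <- bl$bleach_exposure_s
    truth$episodes <- bind$episodes
    traj <- intensity_trajectory(times, signal + noise,
                                 exposure = config$exposure,
                                 period = config$frame_interval,
                                 source_focus_id = truth$emitter_id)
    attr(traj, "truth") <- truth
    traj
  })
}

# Pixel-integrated isotropic Gaussian PSF: expected counts in each pixel of
# the field for total intensity `amp` centred at (x0, y0) (0-based, pixel
# centre at integer coordinates).
render_psf <- function(field_shape, x0, y0, sigma, amp) {
  h <- field_shape[1]; w <- field_shape[2]
  px <- 0:(w - 1); py <- 0:(h - 1)
  fx <- stats::pnorm(px + 0.5, x0, sigma) - stats::pnorm(px - 0.5, x0, sigma)
  fy <- stats::pnorm(py + 0.5, y0, sigma) - stats::pnorm(py - 0.5, y0, sigma)
  amp * outer(fy, fx)
}

#' Simulate a fluorescence movie
#'
#' Renders each emitter as a pixel-integrated 2-D Gaussian PSF, adds the
#' uniform background, applies Poisson shot noise, then the electronic
#' offset and Gaussian read noise. With zero emitters, background and read
#' noise every pixel equals `offset` exactly.
#'
#' @param config A [sim_config()].
#' @param truths List of [emitter_truth()] objects; all emitters must lie
#'   inside the field.
#' @param telegraph Optional [telegraph_params()] shared by telegraph
#'   emitters.
#' @param seed Seed; defaults to `config$seed`.
#' @return An `sm_movie` (see [movie()]) with attribute `"truth"`: a list
#'   of echoed truths as in [simulate_trajectory()].
#' @export
simulate_movie <- function(config, truths, telegraph = NULL,
                           seed = config$seed) {
  h <- config$field_shape[1]; w <- config$field_shape[2]
  for (tr in truths)
    if (tr$x < 0 || tr$x > w - 1 || tr$y < 0 || tr$y > h - 1)
      stopf("emitter %d at (%.1f, %.1f) lies outside the %d x %d field",
            tr$emitter_id, tr$x, tr$y, h, w)
  with_seed(seed, {
    n <- config$n_frames
    times <- (seq_len(n) - 1) * config$frame_interval
    frames <- array(0, dim = c(n, h, w))
    truth_out <- vector("list", length(truths))
    for (i in seq_along(truths)) {
      tr <- truths[[i]]
      dye_counts <- tr$dye_counts %||%
        draw_dye_counts(tr$n_hexamers, config$dol_lambda, config$max_dyes,
                        config$dye_model)
      n_dyes <- sum(dye_counts)
      bl <- simulate_bleaching(n_dyes, config$bleach_tau, n, config$exposure)
      bind <- simulate_binding(tr, telegraph, times, config$exposure,
                               t_end = n * config$frame_interval)
      active <- if (n_dyes > 0) colSums(bl$survive_frac) else rep(0, n)
      amp <- active * config$photons_per_dye_per_frame *
        as.numeric(bind$bound)
      for (k in seq_len(n)) {
        if (amp[k] <= 0) next
        xk <- tr$x + tr$vx * times[k]
        yk <- tr$y + tr$vy * times[k]
        frames[k, , ] <- frames[k, , ] +
          render_psf(config$field_shape, xk, yk, config$psf_sigma, amp[k])
      }
      tr$dye_counts <- dye_counts
      tr$dye_bleach_exposure_s <- bl$bleach_exposure_s
      tr$episodes <- bind$episodes
      truth_out[[i]] <- tr
    }
    for (k in seq_len(n)) {
      lam <- frames[k, , ] + config$background_rate
      shot <- if (any(lam > 0))
        matrix(stats::rpois(h * w, lam), h, w) else matrix(0, h, w)
      read <- if (config$read_noise_sd > 0)
        matrix(stats::rnorm(h * w, 0, config$read_noise_sd), h, w) else 0
      frames[k, , ] <- shot + config$offset + read
    }
    mv <- movie(frames, times, channel_label = "sim",
                pixel_size = config$pixel_size)
    attr(mv, "truth") <- truth_out
    mv
  })
}

#' Simulate a replication-fork scenario
#'
#' Emulates flow-stretched rolling-circle replication: an anchored emitter
#' translates along x at `fork_speed` (the moving fork), while transient
#' emitters appear at the instantaneous fork position as a telegraph
#' process. If the fork would leave the field the movie is truncated at the
#' last in-field frame and a warning is recorded in the returned truth.
#'
#' @param config A [sim_config()].
#' @param fork_speed Fork velocity along x, px/s.
#' @param anchored An [emitter_truth()] for the fork-tracking emitter.
#' @param transients Optional [telegraph_params()] for transient binders at
#'   the fork.
#' @param seed Seed; defaults to `config$seed`.
#' @return An `sm_movie` with `"truth"` attribute; attribute
#'   `"truncated_at_frame"` is set when the fork left the field.
#' @export
simulate_fork_scenario <- function(config, fork_speed, anchored,
                                   transients = NULL, seed = config$seed) {
  w <- config$field_shape[2]
  anchored$vx <- fork_speed
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  xs <- anchored$x + fork_speed * times
  inside <- xs >= 0 & xs <= w - 1
  truncated <- NULL
  if (!all(inside)) {
    last <- max(which(inside))
    truncated <- last
    warnf("fork leaves the field at frame %d; movie truncated", last)
    config$n_frames <- last
  }
  truths <- list(anchored)
  if (!is.null(transients)) {
    follower <- emitter_truth(emitter_id = anchored$emitter_id + 1L,
                              x = anchored$x, y = anchored$y,
                              n_hexamers = 1L,
                              kinetics_class = "transient-telegraph",
                              vx = fork_speed)
    truths <- c(truths, list(follower))
  }
  mv <- simulate_movie(config, truths, telegraph = transients, seed = seed)
  if (!is.null(truncated)) attr(mv, "truncated_at_frame") <- truncated
  mv
}

#' Write a ground-truth sidecar
#'
#' Serialises the `"truth"` attribute of a simulated movie or trajectory to
#' a JSON file next to the data, as required for parameter-recovery tests.
#'
#' @param x A simulated movie or trajectory carrying a `"truth"` attribute.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(x, path) {
  truth <- attr(x, "truth")
  if (is.null(truth)) stopf("no `truth` attribute on this object")
  if (inherits(truth, "emitter_truth")) truth <- list(truth)
  out <- lapply(truth, function(tr) {
    tr <- unclass(tr)
    tr$episodes <- if (!is.null(tr$episodes))
      as.data.frame(tr$episodes) else NULL
    tr
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
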