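# Sub-pixel focus detection, intensity extraction and trajectory linking.

# Least-squares 2-D Gaussian fit in a square window. Returns NULL when the
# fit fails or is degenerate. Coordinates are 0-based with pixel centres at
# integer positions.
fit_gaussian_2d <- function(window_vals, x_coords, y_coords, start,
                            sigma_bounds = c(0.5, 3)) {
  # window_vals is indexed [y, x]; as.vector() is column-major so y varies
  # fastest within each x block
  df <- data.frame(v = as.vector(window_vals),
                   x = rep(x_coords, each = length(y_coords)),
                   y = rep(y_coords, times = length(x_coords)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + b,
      data = df,
      start = start,
      lower = c(A = 0, x0 = min(x_coords), y0 = min(y_coords),
                s = 0.1, b = -Inf),
      upper = c(A = Inf, x0 = max(x_coords), y0 = max(y_coords),
                s = 10, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- as.list(stats::coef(fit))
  if (p$s < sigma_bounds[1] || p$s > sigma_bounds[2]) return(NULL)
  p
}

#' Detect diffraction-limited foci in a frame
#'
#' Candidate local maxima above `median + min_snr * MAD` of the frame are
#' refined by least-squares 2-D Gaussian fitting in a square window,
#' yielding sub-pixel centroids, fitted widths and integrated intensities
#' (`2 * pi * A * sigma^2`, background-subtracted). Degenerate fits (width
#' outside `sigma_bounds`) are discarded and counted; duplicate detections
#' within 1 px are merged keeping the brighter focus.
#'
#' @param frame 2-D numeric array (y, x) in counts.
#' @param min_snr Detection threshold in robust noise units.
#' @param window Odd fitting-window size in px (>= 5).
#' @param sigma_bounds Acceptable fitted PSF width range, px.
#' @return A data frame of class `focus_table` with columns `x`, `y`
#'   (0-based px), `intensity` (integrated, background-subtracted),
#'   `background`, `sigma`, and attribute `"n_discarded"`.
#' @export
detect_foci <- function(frame, min_snr = 5, window = 7L,
                        sigma_bounds = c(0.5, 3)) {
  if (window %% 2 == 0 || window < 5)
    stopf("`window` must be odd and >= 5")
  h <- nrow(frame); w <- ncol(frame)
  med <- stats::median(frame)
  noise <- stats::mad(frame)
  thr <- med + min_snr * noise
  out <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                    background = numeric(0), sigma = numeric(0))
  n_discarded <- 0L
  if (noise == 0 && all(frame == med)) {
    attr(out, "n_discarded") <- 0L
    class(out) <- c("focus_table", class(out))
    return(out)
  }
  half <- (window - 1L) %/% 2L
  # local maxima in a 3x3 neighbourhood, above threshold, away from edges
  cand <- which(frame > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (r <= half || r > h - half || c <= half || c > w - half) next
    nb <- frame[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- frame[r, c] >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  res <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    ys <- (r - half):(r + half); xs <- (c - half):(c + half)
    vals <- frame[ys, xs]
    start <- list(A = frame[r, c] - med, x0 = c - 1, y0 = r - 1,
                  s = 1.3, b = med)
    p <- fit_gaussian_2d(vals, xs - 1, ys - 1, start, sigma_bounds)
    if (is.null(p)) { n_discarded <- n_discarded + 1L; next }
    res[[length(res) + 1]] <- data.frame(
      x = p$x0, y = p$y0, intensity = 2 * pi * p$A * p$s^2,
      background = p$b, sigma = p$s)
  }
  if (length(res)) out <- do.call(rbind, res)
  # merge duplicates within 1 px, keeping the brighter focus
  if (nrow(out) > 1) {
    o <- order(-out$intensity)
    out <- out[o, ]
    kept <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!kept[i]) next
      if (i < nrow(out)) {
        j <- (i + 1):nrow(out)
        d <- sqrt((out$x[j] - out$x[i])^2 + (out$y[j] - out$y[i])^2)
        kept[j[d < 1]] <- FALSE
      }
    }
    out <- out[kept, ]
    out <- out[order(out$y, out$x), ]
  }
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_discarded
  class(out) <- c("focus_table", class(out))
  out
}

#' Integrated focus intensity with local background subtraction
#'
#' Sums pixel counts in a disc around the focus and subtracts the median of
#' an annulus (robust to neighbouring spots) times the disc pixel count.
#'
#' @param frame 2-D numeric array, or an [movie()] (with `frame_index`).
#' @param x,y Focus centre, 0-based px.
#' @param disc_radius Signal disc radius, px.
#' @param annulus `c(r_in, r_out)` background annulus radii, px; `r_in`
#'   must be >= `disc_radius`.
#' @param frame_index Frame to use when `frame` is a movie (1-based).
#' @return Background-subtracted integrated intensity in counts, or `NA`
#'   with a warning when the annulus does not fit in the frame.
#' @export
integrated_intensity <- function(frame, x, y, disc_radius = 4,
                                 annulus = c(6, 9), frame_index = 1L) {
  if (inherits(frame, "sm_movie")) frame <- frame$frames[frame_index, , ]
  if (annulus[1] < disc_radius || annulus[2] <= annulus[1])
    stopf("annulus must satisfy disc_radius <= r_in < r_out")
  h <- nrow(frame); w <- ncol(frame)
  if (x - annulus[2] < 0 || x + annulus[2] > w - 1 ||
      y - annulus[2] < 0 || y + annulus[2] > h - 1) {
    warnf("focus at (%.1f, %.1f) too close to the edge; excluded", x, y)
    return(NA_real_)
  }
  px <- 0:(w - 1); py <- 0:(h - 1)
  dist2 <- outer((py - y)^2, (px - x)^2, `+`)
  disc <- dist2 <= disc_radius^2
  ann <- dist2 >= annulus[1]^2 & dist2 <= annulus[2]^2
  bg <- stats::median(frame[ann])
  sum(frame[disc]) - bg * sum(disc)
}

#' Extract an intensity trajectory for a fixed focus position
#'
#' Applies [integrated_intensity()] to every frame of a movie at one
#' (possibly moving) position.
#'
#' @param mv An [movie()].
#' @param x,y Focus position at the first frame, 0-based px.
#' @param vx,vy Drift in px/s for moving foci.
#' @param ... Passed to [integrated_intensity()].
#' @return An [intensity_trajectory()].
#' @export
extract_trajectory <- function(mv, x, y, vx = 0, vy = 0, ...) {
  n <- dim(mv$frames)[1]
  vals <- vapply(seq_len(n), function(k) {
    t <- mv$times[k]
    suppressWarnings(
      integrated_intensity(mv$frames[k, , ], x + vx * t, y + vy * t, ...))
  }, numeric(1))
  dt <- if (n > 1) stats::median(diff(mv$times)) else NA_real_
  intensity_trajectory(mv$times, vals, exposure = dt, period = dt)
}

#' Link per-frame foci into trajectories
#'
#' Greedy nearest-neighbour linking frame to frame: candidate links are
#' sorted by ascending distance (ties broken by lowest focus index), links
#' farther than `max_step` are rejected, and tracks missing for up to
#' `max_gap` frames may be resumed.
#'
#' @param foci_by_frame Data frame with columns `frame` (integer), `x`,
#'   `y`, and optionally `intensity`; or a list of per-frame
#'   [detect_foci()] tables.
#' @param max_step Maximum link distance per frame step, px.
#' @param max_gap Maximum number of missed frames a track survives.
#' @return A list of data frames (one per trajectory) with columns
#'   `frame`, `x`, `y`, `intensity`.
#' @export
link_trajectories <- function(foci_by_frame, max_step = 3, max_gap = 0L) {
  if (is.list(foci_by_frame) && !is.data.frame(foci_by_frame)) {
    dfs <- lapply(seq_along(foci_by_frame), function(k) {
      f <- foci_by_frame[[k]]
      if (nrow(f) == 0) return(NULL)
      data.frame(frame = k - 1L, x = f$x, y = f$y,
                 intensity = if ("intensity" %in% names(f)) f$intensity
                             else NA_real_)
    })
    foci_by_frame <- do.call(rbind, dfs)
  }
  if (is.null(foci_by_frame) || nrow(foci_by_frame) == 0) return(list())
  if (!"intensity" %in% names(foci_by_frame))
    foci_by_frame$intensity <- NA_real_
  foci_by_frame <- foci_by_frame[order(foci_by_frame$frame), ]
  tracks <- list()           # each: df plus last position/frame
  active <- integer(0)       # indices into tracks
  for (fr in sort(unique(foci_by_frame$frame))) {
    cur <- foci_by_frame[foci_by_frame$frame == fr, , drop = FALSE]
    # drop tracks that have been silent too long
    if (length(active)) {
      silent <- vapply(tracks[active], function(t)
        fr - t$last_frame > max_gap + 1, logical(1))
      active <- active[!silent]
    }
    assigned_focus <- rep(FALSE, nrow(cur))
    if (length(active) && nrow(cur)) {
      lastx <- vapply(tracks[active], function(t) t$last_x, numeric(1))
      lasty <- vapply(tracks[active], function(t) t$last_y, numeric(1))
      d <- sqrt(outer(lasty, cur$y, `-`)^2 + outer(lastx, cur$x, `-`)^2)
      cand <- which(d <= max_step, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        used_track <- rep(FALSE, length(active))
        for (i in seq_len(nrow(cand))) {
          ti <- cand[i, 1]; fi <- cand[i, 2]
          if (used_track[ti] || assigned_focus[fi]) next
          used_track[ti] <- TRUE; assigned_focus[fi] <- TRUE
          tk <- active[ti]
          tracks[[tk]]$df <- rbind(tracks[[tk]]$df,
            data.frame(frame = fr, x = cur$x[fi], y = cur$y[fi],
                       intensity = cur$intensity[fi]))
          tracks[[tk]]$last_x <- cur$x[fi]
          tracks[[tk]]$last_y <- cur$y[fi]
          tracks[[tk]]$last_frame <- fr
        }
      }
    }
    for (fi in which(!assigned_focus)) {
      tracks[[length(tracks) + 1]] <- list(
        df = data.frame(frame = fr, x = cur$x[fi], y = cur$y[fi],
                        intensity = cur$intensity[fi]),
        last_x = cur$x[fi], last_y = cur$y[fi], last_frame = fr)
      active <- c(active, length(tracks))
    }
  }
  lapply(tracks, function(t) { rownames(t$df) <- NULL; t$df })
}

#' Write a focus table as CSV
#'
#' Columns `frame,x_px,y_px,intensity,background,sigma_px`.
#'
#' @param foci A [detect_foci()] table (optionally with a `frame` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_foci_csv <- function(foci, path) {
  df <- data.frame(frame = if ("frame" %in% names(foci)) foci$frame else 0L,
                   x_px = foci$x, y_px = foci$y,
                   intensity = foci$intensity,
                   background = foci$background, sigma_px = foci$sigma)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
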