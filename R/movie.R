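#' Fluorescence movie container
#'
#' A time-ordered image stack for one channel, stored as a numeric array
#' `[frame, y, x]` in camera counts with physical frame times.
#'
#' @param frames 3-D numeric array `(time, y, x)`.
#' @param times Frame times in seconds, strictly increasing.
#' @param channel_label Channel name.
#' @param pixel_size Pixel size in nm.
#' @param offset_corrected Whether the electronic offset has been removed.
#' @return An object of class `sm_movie`.
#' @export
movie <- function(frames, times, channel_label = "", pixel_size = NA_real_,
                  offset_corrected = FALSE) {
  if (length(dim(frames)) != 3)
    stopf("`frames` must be a 3-D array (time, y, x)")
  if (dim(frames)[1] != length(times))
    stopf("`times` must have one entry per frame")
  if (length(times) > 1 && any(diff(times) <= 0))
    stopf("`times` must be strictly increasing")
  if (offset_corrected && any(frames < 0))
    stopf("offset-corrected frames must be non-negative")
  structure(list(frames = frames, times = as.numeric(times),
                 channel_label = channel_label, pixel_size = pixel_size,
                 offset_corrected = offset_corrected),
            class = "sm_movie")
}

#' @export
print.sm_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<sm_movie> '%s': %d frames of %d x %d px, %.1f-%.1f s%s\n",
              x$channel_label, d[1], d[2], d[3], min(x$times), max(x$times),
              if (x$offset_corrected) " (offset-corrected)" else ""))
  invisible(x)
}

#' Write / read a movie as multipage TIFF plus a frame-time CSV
#'
#' Movies are stored as 16-bit unsigned multipage TIFF (one file per
#' channel) with frame times in a CSV sidecar (`frame,t_seconds`). Counts
#' are clamped to `[0, 65535]` and rounded on write.
#'
#' @param mv An [movie()] object.
#' @param path TIFF path; the times sidecar is written next to it as
#'   `<path>.times.csv`.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns an [movie()].
#' @export
write_movie_tiff <- function(mv, path) {
  n <- dim(mv$frames)[1]
  pages <- lapply(seq_len(n), function(k) {
    fr <- round(pmin(pmax(mv$frames[k, , ], 0), 65535))
    fr / 65535            # tiff package stores [0,1] scaled samples
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  utils::write.csv(data.frame(frame = seq_len(n) - 1L,
                              t_seconds = mv$times),
                   paste0(path, ".times.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param channel_label,pixel_size Metadata for the reconstructed movie.
#' @export
read_movie_tiff <- function(path, channel_label = "", pixel_size = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0, dim = c(length(pages), h, w))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]] * 65535
  tf <- paste0(path, ".times.csv")
  times <- if (file.exists(tf)) utils::read.csv(tf)$t_seconds
           else seq_len(length(pages)) - 1
  movie(frames, times, channel_label = channel_label,
        pixel_size = pixel_size)
}

#' Correct a movie for electronic offset and excitation-beam profile
#'
#' Subtracts the camera offset and divides by the beam profile after
#' normalising the profile to unit mean, so overall intensity scale is
#' preserved while illumination inhomogeneity is flattened. Negative
#' residuals after offset subtraction are clipped to zero and counted.
#'
#' @param mv An [movie()].
#' @param offset Electronic offset in counts.
#' @param beam_profile 2-D array matching the frame shape, strictly
#'   positive. Defaults to a uniform profile.
#' @return A corrected [movie()] with attribute `"n_clipped"` giving the
#'   number of clipped pixels.
#' @export
correct_movie <- function(mv, offset, beam_profile = NULL) {
  d <- dim(mv$frames)
  if (is.null(beam_profile)) beam_profile <- matrix(1, d[2], d[3])
  if (!all(dim(beam_profile) == d[2:3]))
    stopf("`beam_profile` must match the frame shape (%d x %d)", d[2], d[3])
  if (any(beam_profile <= 0))
    stopf("`beam_profile` must be strictly positive")
  profile <- beam_profile / mean(beam_profile)
  out <- mv$frames - offset
  n_clipped <- sum(out < 0)
  out[out < 0] <- 0
  for (k in seq_len(d[1])) out[k, , ] <- out[k, , ] / profile
  res <- movie(out, mv$times, channel_label = mv$channel_label,
               pixel_size = mv$pixel_size, offset_corrected = TRUE)
  attr(res, "n_clipped") <- n_clipped
  res
}

# Bilinear interpolation of one frame at (x, y) in 0-based pixel
# coordinates; out-of-field samples take the nearest edge value.
interp_frame <- function(frame, x, y) {
  h <- nrow(frame); w <- ncol(frame)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  idx <- function(r, c) frame[cbind(r + 1, c + 1)]
  (1 - fy) * ((1 - fx) * idx(y0, x0) + fx * idx(y0, x1)) +
    fy * ((1 - fx) * idx(y1, x0) + fx * idx(y1, x1))
}

#' Build a kymograph along a line
#'
#' Space-time image: each row is the intensity profile along the given line
#' in one frame, averaged across `width` perpendicular pixels — the
#' standard visualisation of replication forks on flow-stretched DNA.
#'
#' @param mv An [movie()].
#' @param line List with `start = c(x, y)` and `end = c(x, y)` in 0-based
#'   pixel coordinates.
#' @param width Perpendicular averaging width in pixels (odd).
#' @param spacing Sample spacing along the line in pixels.
#' @return An object of class `kymograph`: list with `image` (time x
#'   position), `line`, `times`, `positions` (px along the line).
#' @export
make_kymograph <- function(mv, line, width = 1L, spacing = 1) {
  dx <- line$end[1] - line$start[1]
  dy <- line$end[2] - line$start[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stopf("zero-length kymograph line")
  ux <- dx / len; uy <- dy / len      # along-line unit vector
  px <- -uy; py <- ux                 # perpendicular unit vector
  s <- seq(0, len, by = spacing)
  offs <- seq_len(width) - (width + 1) / 2
  n <- dim(mv$frames)[1]
  img <- matrix(0, nrow = n, ncol = length(s))
  for (k in seq_len(n)) {
    acc <- 0
    for (o in offs) {
      xs <- line$start[1] + ux * s + px * o
      ys <- line$start[2] + uy * s + py * o
      acc <- acc + interp_frame(mv$frames[k, , ], xs, ys)
    }
    img[k, ] <- acc / length(offs)
  }
  structure(list(image = img, line = line, times = mv$times,
                 positions = s), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (%.1f px)\n",
              nrow(x$image), ncol(x$image), max(x$positions)))
  invisible(x)
}

#' Write a kymograph as TIFF plus times CSV
#'
#' @param kym A [make_kymograph()] result.
#' @param path TIFF path; times go to `<path>.times.csv`.
#' @return `path`, invisibly.
#' @export
write_kymograph_tiff <- function(kym, path) {
  img <- round(pmin(pmax(kym$image, 0), 65535)) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  utils::write.csv(data.frame(frame = seq_len(nrow(kym$image)) - 1L,
                              t_seconds = kym$times),
                   paste0(path, ".times.csv"), row.names = FALSE)
  invisible(path)
}
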