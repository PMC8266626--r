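#' Intensity trajectory
#'
#' Background-subtracted intensity versus time for one tracked focus,
#' together with its excitation schedule (needed to convert wall-clock time
#' into cumulative exposure for photobleaching analysis).
#'
#' @param times Frame times in seconds, strictly increasing.
#' @param intensities Background-subtracted intensities in counts.
#' @param exposure Excitation window per frame, seconds.
#' @param period Frame-to-frame interval, seconds.
#' @param source_focus_id Identifier linking back to a detected focus.
#' @return An object of class `intensity_trajectory`.
#' @export
intensity_trajectory <- function(times, intensities, exposure = NA_real_,
                                 period = NA_real_,
                                 source_focus_id = NA_integer_) {
  if (length(times) != length(intensities))
    stopf("`times` and `intensities` must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stopf("`times` must be strictly increasing")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 exposure = exposure, period = period,
                 source_focus_id = source_focus_id),
            class = "intensity_trajectory")
}

#' @export
print.intensity_trajectory <- function(x, ...) {
  cat(sprintf("<intensity_trajectory> %d frames over %.1f s (focus %s)\n",
              length(x$times), diff(range(x$times)),
              as.character(x$source_focus_id)))
  invisible(x)
}

#' @export
length.intensity_trajectory <- function(x) length(x$times)

#' Read / write trajectories as CSV
#'
#' Plain two-column CSV (`time_s,intensity`); the excitation schedule is
#' stored in commented header lines so a round trip preserves it.
#'
#' @param traj An [intensity_trajectory()].
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns an [intensity_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exposure_s=%g period_s=%g focus_id=%s",
                     traj$exposure, traj$period,
                     as.character(traj$source_focus_id)), con)
  utils::write.csv(data.frame(time_s = traj$times,
                              intensity = traj$intensities),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  header <- readLines(path, n = 1)
  exposure <- period <- NA_real_
  focus_id <- NA_integer_
  if (startsWith(header, "#")) {
    m <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
    kv <- strsplit(m, "=", fixed = TRUE)
    for (p in kv) {
      if (p[1] == "exposure_s") exposure <- suppressWarnings(as.numeric(p[2]))
      if (p[1] == "period_s") period <- suppressWarnings(as.numeric(p[2]))
      if (p[1] == "focus_id") focus_id <- suppressWarnings(as.integer(p[2]))
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  intensity_trajectory(df$time_s, df$intensity, exposure = exposure,
                       period = period, source_focus_id = focus_id)
}
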