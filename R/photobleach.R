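# Photobleaching-step analysis: change-point segmentation of bleaching
# traces, step counting, single-fluorophore intensity calibration and
# Poisson degree-of-labelling estimation.

# Residual sum of squares of y[a..b] around its mean, from cumulative sums
# (cs = c(0, cumsum(y)), cs2 = c(0, cumsum(y^2))). Vectorised over a/b.
seg_rss <- function(cs, cs2, a, b) {
  n <- b - a + 1
  s <- cs[b + 1] - cs[a]
  (cs2[b + 1] - cs2[a]) - s * s / n
}

total_rss <- function(cs, cs2, cps, n) {
  b <- c(0L, cps, n)
  sum(seg_rss(cs, cs2, b[-length(b)] + 1, b[-1]))
}

# Model-selection criterion for a piecewise-constant Gaussian fit with m
# change points: n*log(RSS/n) + 2*m*log(n). Each change point contributes
# two parameters (location and a new level); the shared variance and first
# level are common to all models so drop out of comparisons.
cp_bic <- function(rss, n, m) n * log(rss / n + 1e-12) + 2 * m * log(n)

# Best single split of segment (a..b] respecting min_seg; NULL if none fits.
best_split_in <- function(cs, cs2, a, b, min_seg) {
  lo <- a + min_seg - 1
  hi <- b - min_seg
  if (lo > hi) return(NULL)
  ks <- lo:hi
  costs <- seg_rss(cs, cs2, a, ks) + seg_rss(cs, cs2, ks + 1, b)
  k <- ks[which.min(costs)]
  list(k = k, cost = min(costs))
}

# Best pair of splits of segment (a..b] with the two change points at most
# `window` frames apart. A short intermediate level flanked by two steps is
# invisible to any single split (the means of the two halves barely move),
# so greedy segmentation needs this two-split lookahead; the window keeps
# it cheap, and wider-spaced pairs are found by successive single splits.
best_pair_in <- function(cs, cs2, a, b, min_seg, window) {
  lo <- a + min_seg - 1
  hi <- b - min_seg
  if (hi - lo < min_seg) return(NULL)
  best <- NULL
  for (k1 in lo:(hi - min_seg)) {
    k2s <- seq.int(k1 + min_seg, min(k1 + window, hi))
    if (!length(k2s)) next
    costs <- seg_rss(cs, cs2, a, k1) + seg_rss(cs, cs2, k1 + 1, k2s) +
      seg_rss(cs, cs2, k2s + 1, b)
    j <- which.min(costs)
    if (is.null(best) || costs[j] < best$cost)
      best <- list(k = c(k1, k2s[j]), cost = costs[j])
  }
  best
}

# Cycle through change points re-optimising each location exactly while its
# neighbours are fixed, until no move improves the fit.
refine_cps <- function(cs, cs2, cps, n, min_seg) {
  if (!length(cps)) return(cps)
  repeat {
    changed <- FALSE
    for (i in seq_along(cps)) {
      lo <- if (i == 1) 0L else cps[i - 1]
      hi <- if (i == length(cps)) n else cps[i + 1]
      ks <- seq.int(lo + min_seg, hi - min_seg)
      if (!length(ks)) next
      costs <- seg_rss(cs, cs2, lo + 1, ks) + seg_rss(cs, cs2, ks + 1, hi)
      k <- ks[which.min(costs)]
      if (k != cps[i]) { cps[i] <- k; changed <- TRUE }
    }
    if (!changed) break
  }
  cps
}

#' Detect photobleaching steps by change-point segmentation
#'
#' Segments a bleaching trace into piecewise-constant levels by recursive
#' binary segmentation: at each round the best additional split (minimum
#' squared error) is proposed, change-point locations are refined by
#' coordinate descent, and the enlarged model is kept only if it improves
#' the Bayesian information criterion. A final pruning pass removes any
#' change point whose removal improves the criterion. Downward level
#' transitions count as photobleaching steps; upward transitions
#' (blinking/arrivals) remain change points but are not counted as steps.
#'
#' @param traj An [intensity_trajectory()] or numeric vector of
#'   intensities.
#' @param min_segment Minimum segment length in frames.
#' @param penalty Model-selection criterion; only `"bic"` is implemented.
#' @return An object of class `step_fit`: list with `change_points`
#'   (indices of the last frame of each segment but the final one,
#'   1-based), `levels` (per-segment means), `n_down_steps`,
#'   `n_up_steps`, `residual_ss`, `n`, `min_segment`.
#' @export
detect_steps <- function(traj, min_segment = 3L, penalty = "bic") {
  y <- if (inherits(traj, "intensity_trajectory")) traj$intensities
       else as.numeric(traj)
  n <- length(y)
  if (n < 2 * min_segment)
    stopf("trajectory too short: %d frames < 2 * min_segment", n)
  if (penalty != "bic") stopf("only the 'bic' penalty is implemented")
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  cps <- integer(0)
  lookahead <- 4L * min_segment
  repeat {
    cur_bic <- cp_bic(total_rss(cs, cs2, cps, n), n, length(cps))
    bounds <- c(0L, cps, n)
    # refined single-split candidates from every segment
    best <- NULL
    for (i in seq_len(length(bounds) - 1)) {
      sp <- best_split_in(cs, cs2, bounds[i] + 1, bounds[i + 1], min_segment)
      if (is.null(sp)) next
      cand <- refine_cps(cs, cs2, sort(c(cps, sp$k)), n, min_segment)
      bic <- cp_bic(total_rss(cs, cs2, cand, n), n, length(cand))
      if (is.null(best) || bic < best$bic) best <- list(cps = cand, bic = bic)
    }
    if (!is.null(best) && best$bic < cur_bic) { cps <- best$cps; next }
    # two-split lookahead for short hidden levels
    best <- NULL
    for (i in seq_len(length(bounds) - 1)) {
      sp <- best_pair_in(cs, cs2, bounds[i] + 1, bounds[i + 1], min_segment,
                         lookahead)
      if (is.null(sp)) next
      cand <- refine_cps(cs, cs2, sort(c(cps, sp$k)), n, min_segment)
      bic <- cp_bic(total_rss(cs, cs2, cand, n), n, length(cand))
      if (is.null(best) || bic < best$bic) best <- list(cps = cand, bic = bic)
    }
    if (!is.null(best) && best$bic < cur_bic) { cps <- best$cps; next }
    break
  }
  repeat {
    if (!length(cps)) break
    cur_bic <- cp_bic(total_rss(cs, cs2, cps, n), n, length(cps))
    improved <- FALSE
    for (i in seq_along(cps)) {
      alt <- refine_cps(cs, cs2, cps[-i], n, min_segment)
      if (cp_bic(total_rss(cs, cs2, alt, n), n, length(alt)) < cur_bic) {
        cps <- alt; improved <- TRUE; break
      }
    }
    if (!improved) break
  }
  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1), function(i)
    mean(y[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
  dl <- diff(levels)
  structure(list(change_points = as.integer(cps), levels = levels,
                 n_down_steps = sum(dl < 0), n_up_steps = sum(dl > 0),
                 residual_ss = total_rss(cs, cs2, cps, n),
                 n = n, min_segment = as.integer(min_segment)),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d change points (%d down, %d up) over %d frames\n",
              length(x$change_points), x$n_down_steps, x$n_up_steps, x$n))
  cat("  levels:", paste(signif(x$levels, 4), collapse = " -> "), "\n")
  invisible(x)
}

#' Photobleaching-step counts per molecule
#'
#' Collects `n_down_steps` from a list of [detect_steps()] fits. Molecules
#' with zero downward steps are excluded by default: an unlabelled (or
#' instantly dark) molecule is invisible to detection, so observed
#' step-count data are zero-truncated.
#'
#' @param step_fits List of `step_fit` objects.
#' @param include_zero Keep molecules with zero downward steps.
#' @return Integer vector of steps per molecule; `table()` it for the
#'   histogram.
#' @export
count_steps_per_molecule <- function(step_fits, include_zero = FALSE) {
  counts <- vapply(step_fits, function(f) f$n_down_steps, integer(1))
  if (!include_zero) counts <- counts[counts > 0]
  counts
}

#' Poisson degree-of-labelling estimate
#'
#' Maximum-likelihood Poisson mean for the steps-per-molecule histogram.
#' The plain estimator is the sample mean. The zero-truncated variant
#' accounts for the invisibility of unlabelled molecules by solving
#' `lambda / (1 - exp(-lambda)) = mean(counts)` numerically (bisection to
#' `tol`).
#'
#' @param counts Integer step counts per molecule (vector), or a `table`.
#' @param zero_truncated Use the zero-truncated estimator.
#' @param tol Bisection tolerance.
#' @return Estimated `lambda`.
#' @export
fit_poisson_dol <- function(counts, zero_truncated = FALSE, tol = 1e-8) {
  if (is.table(counts))
    counts <- rep(as.integer(names(counts)), as.integer(counts))
  if (length(counts) < 1) stopf("need at least one molecule")
  m <- mean(counts)
  if (!zero_truncated) return(m)
  if (m <= 0)
    stopf("zero-truncated fit undefined for all-zero counts")
  if (m <= 1) {
    if (m < 1) stopf("zero-truncated mean must exceed 1 (got %.3f)", m)
    return(0)
  }
  f <- function(l) l / (1 - exp(-l)) - m
  lo <- 1e-9; hi <- m
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Single-fluorophore intensity calibration
#'
#' Fits a single Gaussian to per-fluorophore intensities — either the
#' last-step drops of bleaching traces (preferred; immune to residual
#' multi-dye contamination) or raw intensities of surface-immobilised
#' single molecules. A clearly better two-component description of the
#' data (BIC margin > 10) flags the calibration as poorly fit by one
#' Gaussian, e.g. for bimodal input.
#'
#' @param values Numeric intensities (counts); >= 20 recommended.
#' @return An object of class `fluor_calibration`: list with `mean`, `sd`,
#'   `n`, `poor_fit`.
#' @export
calibrate_single_fluorophore <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1) stopf("no finite calibration values")
  if (n < 20) warnf("only %d calibration values; >= 20 recommended", n)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  if (m <= 0) stopf("non-positive fitted mean intensity (%.3g)", m)
  poor_fit <- FALSE
  if (n >= 20 && s > 0) {
    f1 <- fit_stoichiometry_mixture(values, k = 1, n_restarts = 1)
    f2 <- fit_stoichiometry_mixture(values, k = 2, n_restarts = 5,
                                    seed = 1L)
    bic1 <- -2 * f1$log_likelihood + 2 * log(n)
    bic2 <- -2 * f2$log_likelihood + 5 * log(n)
    if (bic2 < bic1 - 10) {
      poor_fit <- TRUE
      warnf("calibration data are poorly described by a single Gaussian")
    }
  }
  structure(list(mean = m, sd = s, n = n, poor_fit = poor_fit),
            class = "fluor_calibration")
}

#' Labelling calibration for stoichiometry conversion
#'
#' Bundles the single-fluorophore intensity (from
#' [calibrate_single_fluorophore()]) with the degree of labelling (from
#' [fit_poisson_dol()]): everything needed to convert focus intensities
#' into molecule copy numbers.
#'
#' @param single_fluor_intensity_mean,single_fluor_intensity_sd Gaussian
#'   calibration of one fluorophore's intensity, counts.
#' @param dol_lambda Mean dyes per molecule.
#' @param n_molecules Number of molecules behind the calibration.
#' @return An object of class `labeling_calibration`.
#' @export
labeling_calibration <- function(single_fluor_intensity_mean,
                                 single_fluor_intensity_sd = NA_real_,
                                 dol_lambda, n_molecules = NA_integer_) {
  if (single_fluor_intensity_mean <= 0)
    stopf("single-fluorophore intensity mean must be positive")
  if (dol_lambda < 0) stopf("`dol_lambda` must be >= 0")
  structure(list(single_fluor_intensity_mean = single_fluor_intensity_mean,
                 single_fluor_intensity_sd = single_fluor_intensity_sd,
                 dol_lambda = dol_lambda,
                 n_molecules = n_molecules),
            class = "labeling_calibration")
}

#' @export
print.labeling_calibration <- function(x, ...) {
  cat(sprintf("<labeling_calibration> nu = %.3g +/- %.3g counts/fluorophore, lambda = %.3g (n = %s)\n",
              x$single_fluor_intensity_mean, x$single_fluor_intensity_sd,
              x$dol_lambda, as.character(x$n_molecules)))
  invisible(x)
}
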