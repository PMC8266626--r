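# Copy-number estimation and Gaussian-mixture population fitting.

#' Estimate molecule copy number for one focus
#'
#' Copies = initial intensity / (single-fluorophore intensity x degree of
#' labelling). The initial intensity is the mean of the first
#' `n_initial_frames` background-subtracted intensities, taken before
#' appreciable photobleaching.
#'
#' @param traj An [intensity_trajectory()], or a numeric scalar
#'   initial intensity.
#' @param calib A [labeling_calibration()].
#' @param n_initial_frames Frames averaged for the initial intensity.
#' @return An object of class `stoichiometry_estimate`: list with
#'   `focus_id`, `initial_intensity`, `copies`, `copies_rounded`.
#' @export
estimate_stoichiometry <- function(traj, calib, n_initial_frames = 3L) {
  if (calib$dol_lambda <= 0)
    stopf("stoichiometry undefined for dol_lambda = 0")
  if (calib$single_fluor_intensity_mean <= 0)
    stopf("calibration mean must be positive")
  init <- if (inherits(traj, "intensity_trajectory")) {
    k <- min(n_initial_frames, length(traj$times))
    mean(traj$intensities[seq_len(k)])
  } else as.numeric(traj)
  copies <- init / (calib$single_fluor_intensity_mean * calib$dol_lambda)
  structure(list(
    focus_id = if (inherits(traj, "intensity_trajectory"))
      traj$source_focus_id else NA_integer_,
    initial_intensity = init,
    copies = copies,
    copies_rounded = max(0L, as.integer(round(copies)))
  ), class = "stoichiometry_estimate")
}

# One EM run for a free-mean Gaussian mixture; returns parameters plus the
# log-likelihood trace (non-decreasing by construction of EM).
em_gmm_once <- function(x, k, mu, sg, w, max_iter, tol, sd_floor) {
  n <- length(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    d <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                numeric(n))
    if (k == 1) d <- matrix(d, ncol = 1)
    tot <- rowSums(d); tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    g <- d / tot
    nk <- colSums(g); nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(g * x) / nk
    sg <- sqrt(colSums(g * (x - rep(mu, each = n))^2) / nk)
    if (any(sg < sd_floor)) floored <- TRUE
    sg <- pmax(sg, sd_floor)
    if (it > 5 && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(mu = mu, sg = sg, w = w, ll = ll, ll_trace = ll_trace,
       sd_floored = floored)
}

# One EM run for the integer-constrained mixture: means fixed at m * mu1,
# m = 1..k; sds either free per component or sigma * sqrt(m) (the dye-count
# variance of m hexamers adds, so population width grows as sqrt(m)).
em_gmm_constrained_once <- function(x, k, mu1, sig, w, scaled_sds,
                                    max_iter, tol, sd_floor) {
  n <- length(x)
  m <- seq_len(k)
  sg <- if (scaled_sds) sig * sqrt(m) else rep(sig, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- m * mu1
    d <- vapply(m, function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                numeric(n))
    if (k == 1) d <- matrix(d, ncol = 1)
    tot <- rowSums(d); tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    g <- d / tot
    nk <- colSums(g); nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    # weighted least squares for mu1 with component variances sg^2
    num <- sum(vapply(m, function(j) j * sum(g[, j] * x) / sg[j]^2, 0))
    den <- sum(vapply(m, function(j) j^2 * nk[j] / sg[j]^2, 0))
    mu1 <- num / den
    mu <- m * mu1
    if (scaled_sds) {
      sig <- sqrt(sum(vapply(m, function(j)
        sum(g[, j] * (x - mu[j])^2) / j, 0)) / n)
      if (sig < sd_floor) { sig <- sd_floor; floored <- TRUE }
      sg <- sig * sqrt(m)
    } else {
      sg <- sqrt(vapply(m, function(j)
        sum(g[, j] * (x - mu[j])^2) / nk[j], 0))
      if (any(sg < sd_floor)) floored <- TRUE
      sg <- pmax(sg, sd_floor)
    }
    if (it > 5 && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(mu = m * mu1, sg = sg, w = w, ll = ll, ll_trace = ll_trace,
       sd_floored = floored, mu1 = mu1)
}

#' Fit a Gaussian mixture to copy-number estimates
#'
#' Expectation-maximisation with multiple restarts; the first restart uses
#' quantile-spread initial means, the rest jitter them. The best
#' log-likelihood wins; runs are deterministic under a fixed `seed`.
#' Components are returned sorted by ascending mean. Degenerate components
#' are kept above `sd_floor` and flagged.
#'
#' `mode = "constrained"` ties the means to integer multiples of the
#' single-molecule peak (`means = m * mu1`), as integer copy numbers
#' dictate; with `scaled_sds = TRUE` the component widths are constrained
#' to `sigma * sqrt(m)`, reflecting additive dye-count variance across
#' hexamers. The constrained fit is multi-started over a grid of `mu1`
#' values.
#'
#' @param copies Numeric vector of copy-number estimates.
#' @param k Number of components.
#' @param mode `"free"` or `"constrained"`.
#' @param scaled_sds For the constrained mode, force `sd_m = sigma *
#'   sqrt(m)`.
#' @param n_restarts Number of EM restarts (free mode).
#' @param seed Seed controlling restart jitter.
#' @param max_iter,tol EM iteration controls.
#' @param sd_floor Lower bound on component standard deviations (copies).
#' @return An object of class `mixture_fit`: `k`, `means`, `sds`,
#'   `weights`, `log_likelihood`, `ll_trace` (best run), `mode`,
#'   `sd_floored`, `n`, `bic`.
#' @export
fit_stoichiometry_mixture <- function(copies, k,
                                      mode = c("free", "constrained"),
                                      scaled_sds = FALSE,
                                      n_restarts = 20L, seed = 1L,
                                      max_iter = 500L, tol = 1e-8,
                                      sd_floor = 0.01) {
  mode <- match.arg(mode)
  x <- as.numeric(copies)
  n <- length(x)
  if (n < 10 * k)
    stopf("need at least %d observations for k = %d (got %d)", 10 * k, k, n)
  sx <- stats::sd(x); if (!is.finite(sx) || sx == 0) sx <- sd_floor
  best <- NULL
  with_seed(seed, {
    if (mode == "free") {
      qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      for (r in seq_len(n_restarts)) {
        mu0 <- if (r == 1) qs else sort(qs + stats::rnorm(k, 0, sx / 4))
        run <- em_gmm_once(x, k, mu0, rep(sx / k, k) + sd_floor,
                           rep(1 / k, k), max_iter, tol, sd_floor)
        if (is.null(best) || run$ll > best$ll) best <- run
      }
    } else {
      scale0 <- mean(x) / mean(seq_len(k))
      for (f in c(0.7, 0.85, 1, 1.15, 1.3)) {
        run <- em_gmm_constrained_once(x, k, f * scale0, sx / k + sd_floor,
                                       rep(1 / k, k), scaled_sds,
                                       max_iter, tol, sd_floor)
        if (is.null(best) || run$ll > best$ll) best <- run
      }
    }
  })
  o <- order(best$mu)
  n_par <- if (mode == "free") 3 * k - 1
           else if (scaled_sds) k + 1 else 2 * k
  structure(list(k = as.integer(k), means = best$mu[o], sds = best$sg[o],
                 weights = best$w[o], log_likelihood = best$ll,
                 ll_trace = best$ll_trace, mode = mode,
                 scaled_sds = scaled_sds, sd_floored = best$sd_floored,
                 n = n, bic = -2 * best$ll + n_par * log(n)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d (%s%s), logLik %.2f, n = %d\n",
              x$k, x$mode, if (x$scaled_sds) ", sqrt(m) sds" else "",
              x$log_likelihood, x$n))
  for (j in seq_len(x$k))
    cat(sprintf("  comp %d: mean %.3f, sd %.3f, weight %.3f\n",
                j, x$means[j], x$sds[j], x$weights[j]))
  if (x$sd_floored) cat("  note: a component hit the sd floor\n")
  invisible(x)
}

#' Choose the mixture component count by BIC
#'
#' Fits `k = 1..k_max` free-mode mixtures and returns the BIC-preferred
#' one. Provided as a helper; the population count is usually fixed by the
#' experiment's design.
#'
#' @param copies Copy-number estimates.
#' @param k_max Largest component count to try.
#' @param ... Passed to [fit_stoichiometry_mixture()].
#' @return The winning `mixture_fit`.
#' @export
select_mixture_k <- function(copies, k_max = 5L, ...) {
  fits <- lapply(seq_len(k_max), function(k) {
    if (length(copies) < 10 * k) return(NULL)
    fit_stoichiometry_mixture(copies, k, ...)
  })
  fits <- Filter(Negate(is.null), fits)
  fits[[which.min(vapply(fits, function(f) f$bic, numeric(1)))]]
}
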