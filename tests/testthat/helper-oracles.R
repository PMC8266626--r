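# Independent oracles used by the tests. These deliberately re-derive
# quantities by enumeration or closed form rather than calling the code
# paths they check.

# Exhaustive change-point search: enumerate every placement of up to
# max_cp change points (respecting min_seg) and score each with the same
# piecewise-constant Gaussian BIC the package uses:
#   n * log(RSS / n + 1e-12) + 2 * m * log(n).
# Fully vectorised over combinations so max_cp = 4 on 60 frames is fast.
oracle_best_segmentation <- function(y, min_seg = 3L, max_cp = 3L) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  bic <- function(rss, m) n * log(rss / n + 1e-12) + 2 * m * log(n)
  rss0 <- (cs2[n + 1] - cs2[1]) - (cs[n + 1] - cs[1])^2 / n
  best <- list(cps = integer(0), score = bic(rss0, 0))
  for (m in seq_len(max_cp)) {
    cm <- utils::combn(seq_len(n - 1), m)
    B <- rbind(0L, cm, n)
    ok <- rep(TRUE, ncol(cm))
    for (i in seq_len(nrow(B) - 1)) ok <- ok & (B[i + 1, ] - B[i, ] >= min_seg)
    if (!any(ok)) next
    B <- B[, ok, drop = FALSE]
    rss <- 0
    for (i in seq_len(nrow(B) - 1)) {
      a <- B[i, ] + 1; b <- B[i + 1, ]
      s <- cs[b + 1] - cs[a]
      rss <- rss + (cs2[b + 1] - cs2[a]) - s * s / (b - a + 1)
    }
    sc <- bic(rss, m)
    j <- which.min(sc)
    if (sc[j] < best$score)
      best <- list(cps = B[2:(m + 1), j], score = sc[j])
  }
  as.integer(best$cps)
}

# Random bleaching staircase: descending levels with slight jitter,
# segment lengths drawn uniformly, Gaussian noise.
make_staircase <- function(n_levels, len_range = c(6L, 20L), step = 100,
                           noise_sd = 15, level_jitter = 5) {
  lens <- sample(seq(len_range[1], len_range[2]), n_levels, replace = TRUE)
  levels <- seq(n_levels, 1) * step + stats::rnorm(n_levels, 0, level_jitter)
  list(y = rep(levels, lens) + stats::rnorm(sum(lens), 0, noise_sd),
       change_points = cumsum(lens)[-n_levels],
       n_down = n_levels - 1L)
}

# Composite decay rate for competing exponential processes.
composite_lifetime <- function(tau_off, tau_bleach) {
  1 / (1 / tau_off + 1 / tau_bleach)
}
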