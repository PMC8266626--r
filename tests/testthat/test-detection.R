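# Image correction, focus detection, intensity extraction, linking and
# kymographs.

test_that("offset and uniform-profile correction is plain subtraction", {
  frames <- array(150, dim = c(2, 4, 4))
  mv <- movie(frames, times = 0:1)
  out <- correct_movie(mv, offset = 100)
  expect_true(all(out$frames == 50))
  expect_equal(attr(out, "n_clipped"), 0)
  # offset equal to the image blanks it, with every pixel clipped counted as 0 residual
  out2 <- correct_movie(mv, offset = 150)
  expect_true(all(out2$frames == 0))
})

test_that("beam-profile normalisation halves intensities where the profile doubles", {
  # constructed 4x4: top half profile 1, bottom half profile 2
  profile <- matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4, byrow = TRUE)
  img <- matrix(300, 4, 4)
  mv <- movie(array(img, dim = c(1, 4, 4)), times = 0)
  out <- correct_movie(mv, offset = 0, beam_profile = profile)
  # unit-mean profile rows are (2/3, 2/3, 4/3, 4/3): closed form
  expect_equal(out$frames[1, 1, 1], 300 / (2 / 3))
  expect_equal(out$frames[1, 4, 1], 300 / (4 / 3))
  expect_equal(out$frames[1, 4, 1] / out$frames[1, 1, 1], 0.5)
})

test_that("correction is idempotent under offset 0 and a uniform profile", {
  set.seed(1)
  mv <- movie(array(rpois(32, 50), dim = c(2, 4, 4)), times = 0:1)
  once <- correct_movie(mv, offset = 10)
  twice <- correct_movie(once, offset = 0)
  expect_identical(once$frames, twice$frames)
})

test_that("correction rejects bad profiles", {
  mv <- movie(array(1, dim = c(1, 4, 4)), times = 0)
  expect_error(correct_movie(mv, 0, matrix(1, 3, 3)), "shape")
  expect_error(correct_movie(mv, 0, matrix(0, 4, 4)), "positive")
})

test_that("a blank frame yields no foci", {
  expect_equal(nrow(detect_foci(matrix(7, 32, 32))), 0)
})

test_that("a noiseless Gaussian spot is localised to 1e-3 px", {
  g <- outer(0:31, 0:31, function(y, x)
    500 * exp(-((x - 10.3)^2 + (y - 7.8)^2) / (2 * 1.3^2))) + 10
  f <- detect_foci(g, min_snr = 5)
  expect_equal(nrow(f), 1)
  expect_lt(abs(f$x - 10.3), 1e-3)
  expect_lt(abs(f$y - 7.8), 1e-3)
  expect_equal(f$sigma, 1.3, tolerance = 1e-4)
})

test_that("two well-separated emitters give exactly two foci, localised within 0.2 px RMS", {
  cfg <- sim_config(seed = 23L, field_shape = c(32L, 48L), n_frames = 8L,
                    background_rate = 5, read_noise_sd = 2, offset = 100,
                    bleach_tau = 1e12)
  truths <- list(emitter_truth(1L, x = 12.4, y = 15.2, dye_counts = 6L),
                 emitter_truth(2L, x = 32.7, y = 15.9, dye_counts = 6L))
  mv <- simulate_movie(cfg, truths)
  errs <- c()
  for (k in seq_len(8)) {
    f <- detect_foci(mv$frames[k, , ] - 100, min_snr = 5)
    expect_equal(nrow(f), 2)
    f <- f[order(f$x), ]
    errs <- c(errs,
              (f$x[1] - 12.4)^2 + (f$y[1] - 15.2)^2,
              (f$x[2] - 32.7)^2 + (f$y[2] - 15.9)^2)
  }
  expect_lt(sqrt(mean(errs)), 0.2)
})

test_that("integrated intensity is zero on flat background and captures a Gaussian spot", {
  flat <- matrix(50, 32, 32)
  expect_equal(integrated_intensity(flat, 15, 15), 0)
  # analytic spot with total mass A: a 3-sigma disc holds >= 98 %
  sigma <- 1.3; A <- 5000
  spot <- outer(0:31, 0:31, function(y, x)
    A / (2 * pi * sigma^2) *
      exp(-((x - 16)^2 + (y - 16)^2) / (2 * sigma^2)))
  got <- integrated_intensity(spot, 16, 16, disc_radius = 3 * sigma,
                              annulus = c(8, 12))
  expect_gt(got, 0.98 * A)
  expect_lt(got, 1.005 * A)
})

test_that("integrated intensity is unbiased over repeated noisy draws", {
  cfg <- sim_config(seed = 29L, field_shape = c(24L, 24L), n_frames = 200L,
                    background_rate = 5, read_noise_sd = 2, offset = 0,
                    bleach_tau = 1e12)
  mv <- simulate_movie(cfg, list(emitter_truth(x = 11.5, y = 11.5,
                                               dye_counts = 4L)))
  vals <- vapply(seq_len(200), function(k)
    integrated_intensity(mv$frames[k, , ], 11.5, 11.5, disc_radius = 4,
                         annulus = c(6, 9)), numeric(1))
  emitted <- 4 * cfg$photons_per_dye_per_frame
  # the pixelated 4-px disc captures essentially the whole PSF mass for
  # sigma 1.3 (pixels overhang the nominal radius)
  expect_lt(abs(mean(vals) - emitted), 2 * sd(vals) / sqrt(200))
})

test_that("a focus too close to the edge is flagged and excluded", {
  expect_warning(v <- integrated_intensity(matrix(1, 16, 16), 1, 8),
                 "edge")
  expect_true(is.na(v))
})

test_that("linking keeps one emitter in one full-length trajectory", {
  df <- data.frame(frame = 0:9, x = rep(5, 10) + 0.01 * (0:9), y = 5)
  tr <- link_trajectories(df, max_step = 2)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 10)
})

test_that("two distant emitters never swap identity", {
  set.seed(2)
  frames <- rep(0:19, each = 2)
  df <- data.frame(frame = frames,
                   x = rep(c(5, 25), 20) + rnorm(40, 0, 0.2),
                   y = rep(10, 40))
  tr <- link_trajectories(df, max_step = 3)
  expect_length(tr, 2)
  xs <- vapply(tr, function(d) mean(d$x), numeric(1))
  expect_true(all(abs(sort(xs) - c(5, 25)) < 1))
  for (d in tr) expect_lt(diff(range(d$x)), 2)
})

test_that("a single missed frame is bridged when max_gap allows", {
  df <- data.frame(frame = c(0, 1, 3, 4), x = 5, y = 5)
  tr <- link_trajectories(df, max_step = 2, max_gap = 2L)
  expect_length(tr, 1)
  tr0 <- link_trajectories(df, max_step = 2, max_gap = 0L)
  expect_length(tr0, 2)
})

test_that("a static emitter produces a vertical kymograph stripe and a moving fork a tilted one", {
  cfg <- sim_config(seed = 37L, field_shape = c(16L, 64L), n_frames = 30L,
                    read_noise_sd = 0, background_rate = 0, offset = 0,
                    bleach_tau = 1e12, frame_interval = 1)
  line <- list(start = c(0, 8), end = c(63, 8))
  static <- simulate_movie(cfg, list(emitter_truth(x = 20, y = 8,
                                                   dye_counts = 6L)))
  kym <- make_kymograph(static, line)
  cent0 <- vapply(seq_len(nrow(kym$image)), function(k) {
    row <- kym$image[k, ]
    sum(kym$positions * row) / sum(row)
  }, numeric(1))
  # stripe stays put to within shot-noise centroid jitter
  expect_lt(diff(range(cent0)), 1)
  expect_lt(abs(mean(cent0) - 20), 0.5)
  mvf <- simulate_fork_scenario(cfg, fork_speed = 1.2,
                                anchored = emitter_truth(x = 5, y = 8,
                                                         dye_counts = 6L))
  kymf <- make_kymograph(mvf, line)
  cent <- vapply(seq_len(nrow(kymf$image)), function(k) {
    row <- kymf$image[k, ]
    sum(kymf$positions * row) / sum(row)
  }, numeric(1))
  slope <- coef(lm(cent ~ kymf$times))[2]
  expect_lt(abs(slope - 1.2) / 1.2, 0.05)
})

test_that("a blank movie gives an all-offset kymograph", {
  mv <- movie(array(100, dim = c(5, 16, 16)), times = 0:4)
  kym <- make_kymograph(mv, list(start = c(0, 8), end = c(15, 8)))
  expect_true(all(kym$image == 100))
  expect_equal(nrow(kym$image), 5)
  expect_error(make_kymograph(mv, list(start = c(3, 3), end = c(3, 3))),
               "zero-length")
})

test_that("focus tables and kymographs export to CSV / TIFF", {
  g <- outer(0:31, 0:31, function(y, x)
    500 * exp(-((x - 10)^2 + (y - 12)^2) / (2 * 1.3^2))) + 10
  f <- detect_foci(g, min_snr = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_foci_csv(f, path)
  back <- read.csv(path)
  expect_equal(back$x_px, f$x)
  expect_equal(names(back),
               c("frame", "x_px", "y_px", "intensity", "background",
                 "sigma_px"))
  mv <- movie(array(100, dim = c(4, 16, 16)), times = 0:3)
  kym <- make_kymograph(mv, list(start = c(0, 8), end = c(15, 8)))
  tp <- withr::local_tempfile(fileext = ".tif")
  write_kymograph_tiff(kym, tp)
  expect_true(file.exists(tp))
  expect_true(file.exists(paste0(tp, ".times.csv")))
})

test_that("movies round-trip through 16-bit TIFF with times sidecar", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mv.tif")
  mv <- movie(array(round(runif(2 * 8 * 8, 0, 1000)), dim = c(2, 8, 8)),
              times = c(0, 0.5), channel_label = "red")
  write_movie_tiff(mv, path)
  back <- read_movie_tiff(path, channel_label = "red")
  expect_equal(round(back$frames), mv$frames, tolerance = 1e-8)
  expect_equal(back$times, mv$times)
})
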