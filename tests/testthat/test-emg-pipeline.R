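# sEMG conditioning chain: filter response contracts, RMS windowing,
# normalisation, smoothing, segmentation, peaks.

fs <- 1000
tvec <- seq(0, 2, by = 1 / fs)  # ends on a zero crossing of integer-Hz sines

test_that("notch filter attenuates 50 Hz and passes neighbours", {
  x50 <- sin(2 * pi * 50 * tvec)
  expect_lt(rms(notch_filter(x50, fs)), 0.1 * rms(x50))
  x100 <- sin(2 * pi * 100 * tvec)
  expect_gt(rms(notch_filter(x100, fs)), 0.95 * rms(x100))
  # within +/- 20 Hz of the notch the loss stays under 1 dB
  for (f in c(30, 70)) {
    xf <- sin(2 * pi * f * tvec)
    expect_gt(rms(notch_filter(xf, fs)), 10^(-1 / 20) * rms(xf))
  }
  expect_identical(notch_filter(numeric(2000), fs), numeric(2000))
  expect_error(notch_filter(x50, fs, f0 = 600), "Nyquist")
})

test_that("bandpass filter removes DC/low/high frequencies, passes the band", {
  x <- 1 + sin(2 * pi * 100 * tvec)
  y <- bandpass_filter(x, fs)
  expect_lt(abs(mean(y)), 1e-3)
  expect_gt(rms(y), 0.9 * rms(sin(2 * pi * 100 * tvec)))
  x5 <- sin(2 * pi * 5 * tvec)
  expect_lt(rms(bandpass_filter(x5, fs)), 0.1 * rms(x5))
  x490 <- sin(2 * pi * 490 * tvec)
  expect_lt(rms(bandpass_filter(x490, fs)), 0.1 * rms(x490))
  expect_error(bandpass_filter(x, fs, lo = 0, hi = 450), "invalid band")
  expect_error(bandpass_filter(x, fs, lo = 20, hi = 600), "invalid band")
})

test_that("stopband attenuation contracts hold in dB terms", {
  # >= 20 dB at 5 and 490 Hz relative to the 100 Hz passband response
  db <- function(f) {
    xf <- sin(2 * pi * f * tvec)
    20 * log10(rms(bandpass_filter(xf, fs)) / rms(xf))
  }
  pass_db <- db(100)
  expect_gt(pass_db, -1)
  expect_lt(db(5), pass_db - 20)
  expect_lt(db(490), pass_db - 20)
})

test_that("filters are linear", {
  set.seed(31)
  a <- rnorm(1500); b <- rnorm(1500)
  expect_equal(bandpass_filter(a + b, fs),
               bandpass_filter(a, fs) + bandpass_filter(b, fs),
               tolerance = 1e-8)
  expect_equal(notch_filter(a + b, fs),
               notch_filter(a, fs) + notch_filter(b, fs),
               tolerance = 1e-8)
})

test_that("windowed RMS obeys the count formula and matches brute force", {
  env <- windowed_rms(rep(0.2, 1000), fs)
  expect_identical(length(env$values), (1000L - 100L) %/% 50L + 1L)
  expect_equal(env$values, rep(0.2, 19), tolerance = 1e-12)
  # sine with integer cycles per window: every window is A/sqrt(2)
  x <- sin(2 * pi * 100 * (0:999) / fs)
  env2 <- windowed_rms(x, fs)
  expect_equal(env2$values, rep(1 / sqrt(2), 19), tolerance = 1e-6)
  # brute-force oracle on a random signal
  set.seed(32)
  xr <- rnorm(500)
  env3 <- windowed_rms(xr, fs)
  brute <- vapply(seq(1, 401, by = 50), function(s) sqrt(mean(xr[s:(s + 99)]^2)),
                  numeric(1))
  expect_equal(env3$values, brute, tolerance = 1e-12)
  expect_error(windowed_rms(rnorm(50), fs), "shorter than one window")
})

test_that("normalize_resample interpolates onto 500 points with exact endpoints", {
  ramp <- windowed_rms(rep(1, 1000), fs)
  ramp$values <- seq(2, 20, length.out = 19)
  out <- normalize_resample(ramp)
  expect_length(out$values, 500)
  expect_equal(out$values, seq(2, 20, length.out = 500), tolerance = 1e-12)
  ramp$values <- rep(3.3, 19)
  expect_equal(normalize_resample(ramp)$values, rep(3.3, 500))
  # piecewise-linear oracle at the query points
  set.seed(33)
  ramp$values <- runif(19)
  out2 <- normalize_resample(ramp)
  oracle <- stats::approxfun(seq(0, 1, length.out = 19), ramp$values)
  expect_equal(out2$values, oracle(seq(0, 1, length.out = 500)), tolerance = 1e-12)
  one <- windowed_rms(rep(1, 100), fs)
  expect_error(normalize_resample(one), "at least 2")
})

test_that("gaussian_smooth is unit-area, symmetric and has the closed-form peak", {
  expect_equal(gaussian_smooth(rep(5, 200), sigma = 10), rep(5, 200),
               tolerance = 1e-12)
  imp <- numeric(501); imp[251] <- 1
  sm <- gaussian_smooth(imp, sigma = 10)
  expect_equal(sm[251], 1 / (10 * sqrt(2 * pi)), tolerance = 1e-3)
  x <- dnorm(seq(-3, 3, length.out = 301))
  smx <- gaussian_smooth(x, sigma = 5)
  expect_equal(smx, rev(smx), tolerance = 1e-12)
  expect_error(gaussian_smooth(1:10, sigma = 0), "positive")
})

test_that("mean_rms averages the envelope", {
  env <- windowed_rms(rep(1, 1000), fs)
  env$values <- c(0.1, 0.3)
  expect_equal(mean_rms(env), 0.2)
  set.seed(34)
  env$values <- runif(25)
  expect_equal(mean_rms(env), sum(env$values) / 25)
})

test_that("segmentation: markers take precedence, flat envelopes fail with count", {
  profs <- toy_profiles()
  spec <- cohort_spec(n_participants = 2, reps_per_condition = 5,
                      trial_duration = 10, powerline_amplitude = 0,
                      noise_sd = 0, seed = 8)
  rec <- generate_emg(profs$correct, spec, 0.1, repetition_count = 5, seed = 8)
  env <- emg_envelope(rec)
  via_markers <- segment_repetitions(env, expected = 5,
                                     markers = rec$repetition_markers)
  expect_identical(nrow(via_markers), 5L)
  # marker windows hold essentially all burst energy
  in_marker <- unlist(lapply(seq_len(5), function(i)
    via_markers$start_window[i]:via_markers$end_window[i]))
  expect_gt(sum(env$values[in_marker]^2) / sum(env$values^2), 0.95)

  flat <- windowed_rms(rep(0.2, 2000), fs)
  err <- tryCatch(segment_repetitions(flat, expected = 10),
                  cbeqc_segment_count_error = function(e) e)
  expect_s3_class(err, "cbeqc_segment_count_error")
  expect_identical(err$detected, 0L)
})

test_that("peak RMS per repetition takes the within-segment maximum", {
  env <- windowed_rms(rep(1, 1000), fs)
  env$values <- c(0, 1, 0, 2, 0)
  segs <- data.frame(start_window = c(1, 3), end_window = c(3, 5))
  expect_equal(peak_rms_per_repetition(env, segs), c(1, 2))
  expect_equal(peak_rms_per_repetition(env, data.frame(start_window = 1,
                                                       end_window = 5)), 2)
  set.seed(35)
  env$values <- runif(40)
  segs2 <- data.frame(start_window = c(1, 21), end_window = c(20, 40))
  expect_equal(peak_rms_per_repetition(env, segs2),
               c(max(env$values[1:20]), max(env$values[21:40])))
  expect_error(peak_rms_per_repetition(env, data.frame(start_window = 0,
                                                       end_window = 2)),
               "out of")
})
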