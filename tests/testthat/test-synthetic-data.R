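# Synthetic cohort generator: angle injection, EMG calibration,
# reproducibility, manifest structure.

test_that("noiseless injection reproduces the target angle exactly", {
  spec <- small_spec()
  for (aname in c("right_knee", "right_knee_ankle", "left_hip")) {
    profs <- toy_profiles(mu_cor = 176.95, angle_name = aname)
    lm <- generate_landmark_series(profs$correct, spec, 1, 1)
    ang <- compute_angle_series(lm, default_angle_registry()[[aname]])
    expect_lt(max(abs(ang$values - 176.95)), 1e-6)
    expect_true(all(lm$x >= 0 & lm$x <= 1 & lm$y >= 0 & lm$y <= 1))
  }
  # arbitrary noiseless mean: per-repetition mean is exactly mu
  profs <- toy_profiles(mu_cor = 123.4)
  lm <- generate_landmark_series(profs$correct, spec, 1, 1)
  ang <- compute_angle_series(lm, default_angle_registry()$right_knee_ankle)
  expect_equal(mean_angle(ang), 123.4, tolerance = 1e-9)
})

test_that("angle round trip holds for injected noisy sequences", {
  # recompute the injected draws directly and compare the geometric recovery
  profs <- toy_profiles(mu_cor = 150, sd_within = 2)
  spec <- cohort_spec(n_participants = 2, reps_per_condition = 1,
                      trial_duration = 20, seed = 99)
  lm <- generate_landmark_series(profs$correct, spec, 1, 1)
  ang <- compute_angle_series(lm, default_angle_registry()$right_knee_ankle)
  n <- lm$n_frames
  expect_identical(n, 600L)
  # same pseudo-random draws applied directly to angles (independent path)
  mi <- cbeqc:::.movement_index("M5")
  set.seed(cbeqc:::sub_seed(99, 1L, 1, mi, 1L)); mu_p <- rnorm(1, 150, 0)
  set.seed(cbeqc:::sub_seed(99, 2L, 1, mi, 1L, 1)); eps <- rnorm(n, 0, 2)
  expect_lt(max(abs(ang$values - (mu_p + eps))), 1e-6)
  # sample SD close to the nominal within-frame SD (3 SEs for SD of n draws)
  se_sd <- 2 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(ang$values) - 2), 3 * se_sd)
})

test_that("out-of-range frame realisations are clipped with a warning", {
  profs <- toy_profiles(mu_cor = 179.9, sd_within = 1)
  expect_warning(
    lm <- generate_landmark_series(profs$correct, small_spec(), 1, 1),
    "clipped")
  ang <- compute_angle_series(lm, default_angle_registry()$right_knee_ankle)
  expect_true(all(ang$values > 0 & ang$values < 180))
})

test_that("EMG calibration hits the target mean RMS across the working range", {
  profs <- toy_profiles()
  spec <- cohort_spec(n_participants = 2, reps_per_condition = 3,
                      trial_duration = 6, powerline_amplitude = 0,
                      noise_sd = 0, seed = 5)
  for (target in c(0.02, 0.10, 0.30)) {
    rec <- generate_emg(profs$correct, spec, target, seed = 5)
    m <- mean_rms(emg_envelope(rec))
    expect_gt(m, 0.95 * target)
    expect_lt(m, 1.05 * target)
  }
})

test_that("EMG mean RMS is monotone in the target strength", {
  profs <- toy_profiles()
  spec <- cohort_spec(n_participants = 2, reps_per_condition = 3,
                      trial_duration = 6, seed = 5)
  targets <- c(0.02, 0.05, 0.1, 0.2)
  ms <- vapply(targets, function(s)
    mean_rms(emg_envelope(generate_emg(profs$correct, spec, s, seed = 5))),
    numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("generated bursts are found by threshold segmentation", {
  profs <- toy_profiles()
  spec <- cohort_spec(n_participants = 2, reps_per_condition = 10,
                      trial_duration = 20, powerline_amplitude = 0,
                      noise_sd = 0, seed = 3)
  rec <- generate_emg(profs$correct, spec, 0.1, repetition_count = 10, seed = 3)
  env <- emg_envelope(rec)
  segs <- segment_repetitions(env, expected = 10, markers = NULL)
  expect_identical(nrow(segs), 10L)
  # detected segments overlap the true marker extents
  centers_s <- env$window_start_s[segs$start_window] +
    (env$window_start_s[segs$end_window] - env$window_start_s[segs$start_window]) / 2
  expect_true(all(abs(centers_s - (rec$repetition_markers$start_s +
                                     rec$repetition_markers$end_s) / 2) < 0.5))
})

test_that("too-short trials cannot fit the requested bursts", {
  profs <- toy_profiles()
  spec <- cohort_spec(n_participants = 2, reps_per_condition = 10,
                      trial_duration = 0.05, seed = 3)
  expect_error(generate_emg(profs$correct, spec, 0.1, repetition_count = 10,
                            seed = 3), "too short")
  expect_error(generate_emg(profs$correct, small_spec(), -1), "positive")
})

test_that("cohorts are reproducible and manifest arithmetic holds", {
  profs <- reference_profiles("M2")
  spec <- cohort_spec(n_participants = 4, reps_per_condition = 3,
                      trial_duration = 2, seed = 21)
  c1 <- generate_cohort(profs, spec)
  c2 <- generate_cohort(profs, spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$landmarks, c2$landmarks)
  expect_identical(c1$emg, c2$emg)
  expect_identical(nrow(c1$manifest), 4L * 2L * 3L)
  # different seed changes the draws
  c3 <- generate_cohort(profs, cohort_spec(n_participants = 4,
                                           reps_per_condition = 3,
                                           trial_duration = 2, seed = 22))
  expect_false(identical(c1$landmarks, c3$landmarks))
})

test_that("duplicate or incomplete profile sets are rejected", {
  profs <- reference_profiles("M2")
  expect_error(generate_cohort(c(profs, profs[1]), small_spec()), "duplicate")
  expect_error(generate_cohort(profs[1], small_spec()), "both conditions")
})

test_that("participant strengths are correlated across conditions", {
  profs <- reference_profiles("M3")
  spec <- cohort_spec(n_participants = 20, reps_per_condition = 1,
                      trial_duration = 2, strength_correlation = 0.8, seed = 17)
  coh <- generate_cohort(profs, spec, components = "landmarks")
  s <- coh$strengths
  expect_gt(min(s$strength_correct, s$strength_incorrect), 0.004)
  r <- cor(s$strength_correct, s$strength_incorrect)
  expect_gt(r, 0.5)
  expect_lt(r, 0.95)
})

test_that("write_cohort emits a resolvable manifest", {
  profs <- toy_profiles(sd_within = 0.5)
  spec <- small_spec()
  coh <- generate_cohort(profs, spec)
  dir <- withr::local_tempdir()
  manifest_path <- write_cohort(coh, dir)
  man <- utils::read.csv(manifest_path)
  expect_identical(nrow(man), nrow(coh$manifest))
  expect_true(all(file.exists(man$landmark_path)))
  expect_true(all(file.exists(man$emg_path)))
  back <- read_landmarks(man$landmark_path[1], fps = spec$fps)
  expect_equal(back$x, coh$landmarks[[man$landmark_id[1]]]$x, tolerance = 1e-12)
})
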