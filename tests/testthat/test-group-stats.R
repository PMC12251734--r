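# Cohort aggregation and paired statistics.

test_that("per-participant means equal mu on a noiseless cohort", {
  profs <- toy_profiles(mu_cor = 170, mu_inc = 150)
  spec <- cohort_spec(n_participants = 3, reps_per_condition = 2,
                      trial_duration = 2, powerline_amplitude = 0,
                      noise_sd = 0, seed = 61)
  coh <- generate_cohort(profs, spec, components = "landmarks")
  ppm <- per_participant_means(coh, what = "angle")
  expect_equal(ppm$mean_angle_deg[ppm$condition == "correct"], rep(170, 3),
               tolerance = 1e-9)
  expect_equal(ppm$mean_angle_deg[ppm$condition == "incorrect"], rep(150, 3),
               tolerance = 1e-9)
})

test_that("per-participant means match a brute-force group-by oracle", {
  profs <- toy_profiles(sd_between = 3, sd_within = 1)
  spec <- cohort_spec(n_participants = 3, reps_per_condition = 2,
                      trial_duration = 2, seed = 62)
  coh <- generate_cohort(profs, spec, components = "landmarks")
  ppm <- per_participant_means(coh, what = "angle")
  reg <- default_angle_registry()
  for (i in seq_len(nrow(ppm))) {
    sub <- coh$manifest[coh$manifest$participant_id == ppm$participant_id[i] &
                          coh$manifest$condition == ppm$condition[i], ]
    rep_means <- vapply(sub$landmark_id, function(k)
      mean(compute_angle_series(coh$landmarks[[k]],
                                reg$right_knee_ankle)$values), numeric(1))
    expect_equal(ppm$mean_angle_deg[i], mean(rep_means), tolerance = 1e-9)
  }
})

test_that("summarize_conditions uses the sample SD convention", {
  ppm <- data.frame(
    participant_id = c("P01", "P02", "P01", "P02"),
    movement_id = "M2",
    condition = c("correct", "correct", "incorrect", "incorrect"),
    mean_angle_deg = c(170, 180, 120, 130))
  s <- summarize_conditions(ppm)
  cor_row <- s[s$condition == "correct", ]
  expect_equal(cor_row$angle_mean, 175)
  expect_equal(cor_row$angle_sd, sqrt(50), tolerance = 1e-9)  # 7.071
  expect_identical(cor_row$n_participants, 2L)
})

test_that("condition summaries recover generator parameters within 3 SE", {
  profs <- reference_profiles("M2")  # between-participant SD = printed SD
  spec <- cohort_spec(n_participants = 12, reps_per_condition = 2,
                      trial_duration = 3, seed = 63)
  coh <- generate_cohort(profs, spec)
  ppm <- per_participant_means(coh)
  s <- summarize_conditions(ppm)
  for (cond in c("correct", "incorrect")) {
    prof <- profs[[paste0("M2_", cond)]]
    row <- s[s$condition == cond, ]
    expect_lt(abs(row$angle_mean - prof$angle_mean),
              3 * prof$angle_sd_between / sqrt(12) + 1e-9)
    se_emg <- prof$emg_sd_between / sqrt(12)
    expect_lt(abs(row$emg_mean - prof$emg_mean), 3 * se_emg + 0.05 * prof$emg_mean)
  }
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  res <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t_stat, 2 * sqrt(3), tolerance = 1e-9)
  expect_identical(res$df, 2)
  expect_equal(res$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)
  expect_equal(res$mean_diff, 2)

  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)), "zero-variance")
  expect_error(paired_ttest(1:3, 1:4), "length mismatch")
})

test_that("movement-level tests report raw and Holm-adjusted p-values", {
  profs <- reference_profiles("M3")
  spec <- cohort_spec(n_participants = 10, reps_per_condition = 2,
                      trial_duration = 3, strength_correlation = 0.8, seed = 64)
  coh <- generate_cohort(profs, spec, components = "emg")
  ppm <- per_participant_means(coh, what = "emg")
  tt <- movement_ttests(ppm)
  expect_identical(tt$movement_id, "M3")
  expect_identical(tt$df, 9)
  expect_true(all(tt$p_holm >= tt$p_value))
  expect_gt(tt$mean_diff, 0)
})

test_that("scatter table flags points below the identity line", {
  ppm <- data.frame(
    participant_id = rep(c("P01", "P02"), each = 2),
    movement_id = "M8",
    condition = rep(c("correct", "incorrect"), 2),
    mean_rms_mv = c(0.10, 0.05, 0.05, 0.05))
  st <- scatter_table(ppm, "M8")
  expect_identical(st$below_identity, c(TRUE, FALSE))
  expect_equal(st$correct_mean_mv, c(0.10, 0.05))
  expect_error(scatter_table(ppm, "M1-A"), "absent")
})

test_that("most participants fall below the identity line on a calibrated cohort", {
  profs <- reference_profiles("M3")
  spec <- cohort_spec(n_participants = 16, reps_per_condition = 2,
                      trial_duration = 3, strength_correlation = 0.8, seed = 65)
  coh <- generate_cohort(profs, spec, components = "emg")
  ppm <- per_participant_means(coh, what = "emg")
  st <- scatter_table(ppm, "M3")
  expect_gt(mean(st$below_identity), 0.5)
})

test_that("boxplot table computes interpolated quartiles", {
  bt <- boxplot_table(list(correct = c(1, 2, 3, 4, 5), incorrect = 2))
  s <- bt$summary
  expect_equal(s$median[s$condition == "correct"], 3)
  expect_equal(s$q1[s$condition == "correct"], 2)
  expect_equal(s$q3[s$condition == "correct"], 4)
  expect_equal(s$iqr[s$condition == "correct"], 2)
  expect_true(all(s[s$condition == "incorrect", c("q1", "median", "q3")] == 2))
  set.seed(66)
  v <- runif(10)
  bt2 <- boxplot_table(list(correct = v, incorrect = v))
  expect_equal(bt2$summary$median,
               rep(unname(stats::quantile(v, 0.5, type = 7)), 2))
  expect_identical(nrow(bt2$peaks), 20L)
})
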