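# Small in-code fixtures shared across the suite.

# noiseless single-movement profile pair at chosen means
toy_profiles <- function(movement = "M5", mu_cor = 176.95, mu_inc = 173.19,
                         sd_between = 0, sd_within = 0,
                         emg_cor = 0.13, emg_inc = 0.09, emg_sd = 0.04,
                         angle_name = default_movement_angle(movement)) {
  list(
    correct = movement_profile(movement, "correct", mu_cor, sd_between,
                               sd_within, emg_cor, emg_sd, angle_name),
    incorrect = movement_profile(movement, "incorrect", mu_inc, sd_between,
                                 sd_within, emg_inc, emg_sd, angle_name)
  )
}

small_spec <- function(...) {
  cohort_spec(n_participants = 3, reps_per_condition = 2, trial_duration = 2,
              powerline_amplitude = 0, noise_sd = 0, seed = 7, ...)
}

# linearly separable two-cluster feature table (10 features, binary label)
separable_table <- function(n_per_class = 20, gap = 10, seed = 1) {
  set.seed(seed)
  p <- length(feature_columns())
  x0 <- matrix(rnorm(n_per_class * p), n_per_class, p)
  x1 <- matrix(rnorm(n_per_class * p) + gap, n_per_class, p)
  tbl <- as.data.frame(rbind(x0, x1))
  names(tbl) <- feature_columns()
  tbl$label <- rep(c(0L, 1L), each = n_per_class)
  tbl$participant_id <- sprintf("P%02d", rep(seq_len(n_per_class), 2))
  tbl
}

rms <- function(x) sqrt(mean(x^2))
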