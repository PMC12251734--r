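# Synthetic cohort generator. Landmark trajectories are constructed so that
# the registry angle computed from them reproduces an injected per-frame
# angle sequence exactly; sEMG trials are amplitude-modulated band-limited
# noise bursts calibrated so the post-conditioning mean RMS hits a target
# participant strength.

# Static base pose (normalised image coordinates, y downward) for landmarks
# that do not participate in the scored angle.
.base_pose <- function() {
  rbind("11" = c(0.44, 0.22), "12" = c(0.56, 0.22),
        "23" = c(0.45, 0.52), "24" = c(0.55, 0.52),
        "25" = c(0.43, 0.66), "26" = c(0.57, 0.66),
        "27" = c(0.44, 0.88), "28" = c(0.56, 0.88))
}

# Limb length used when placing the moving endpoint of the scored angle;
# short enough that any target angle keeps coordinates inside [0, 1].
.limb_r <- 0.2

#' Generate one landmark trial realising a target angle process
#'
#' The scored angle (named by `profile$angle_name` in `registry`) follows
#' `theta_t = mu_p + eps_t`, where `mu_p ~ N(angle_mean, angle_sd_between)`
#' is drawn once per (participant, movement, condition) and
#' `eps_t ~ N(0, angle_sd_within)` per frame. The moving endpoint of the
#' angle is placed by rotating a fixed-length limb; all other landmarks sit
#' at plausible static positions. Frame realisations falling outside
#' (0, 180) degrees are clipped with a warning. Deterministic given
#' `spec$seed`, the participant index and the repetition index.
#'
#' @param profile A [movement_profile()].
#' @param spec A [cohort_spec()].
#' @param participant_index,repetition_index 1-based indices.
#' @param registry Angle registry; default [default_angle_registry()].
#' @return A `landmark_series` of `round(trial_duration * fps)` frames.
#' @export
generate_landmark_series <- function(profile, spec, participant_index,
                                     repetition_index,
                                     registry = default_angle_registry()) {
  stopifnot(inherits(profile, "movement_profile"), inherits(spec, "cohort_spec"))
  aspec <- registry[[profile$angle_name]]
  if (is.null(aspec)) stop("angle '", profile$angle_name, "' not in registry")
  mi <- .movement_index(profile$movement_id)
  ci <- .condition_index(profile$condition)

  # participant-level mean, shared across repetitions
  set.seed(sub_seed(spec$seed, 1L, participant_index, mi, ci))
  mu_p <- stats::rnorm(1, profile$angle_mean, profile$angle_sd_between)
  tries <- 0
  while ((mu_p <= 0 || mu_p >= 180) && tries < 100) {
    mu_p <- stats::rnorm(1, profile$angle_mean, profile$angle_sd_between)
    tries <- tries + 1
  }
  if (mu_p <= 0 || mu_p >= 180)
    stop("could not realise a participant mean angle inside (0, 180)")

  n_frames <- as.integer(round(spec$trial_duration * spec$fps))
  set.seed(sub_seed(spec$seed, 2L, participant_index, mi, ci, repetition_index))
  theta <- mu_p + stats::rnorm(n_frames, 0, profile$angle_sd_within)
  out_of_range <- theta <= 0 | theta >= 180
  if (any(out_of_range)) {
    warning(sum(out_of_range), " frame angle realisation(s) outside (0, 180) ",
            "degrees were clipped")
    theta <- pmin(pmax(theta, 1e-4), 180 - 1e-4)
  }

  base <- .base_pose()
  ids <- rownames(base)
  xm <- matrix(rep(base[, 1], each = n_frames), n_frames, length(ids),
               dimnames = list(NULL, ids))
  ym <- matrix(rep(base[, 2], each = n_frames), n_frames, length(ids),
               dimnames = list(NULL, ids))
  th <- theta * pi / 180
  if (aspec$kind == "vertex") {
    pa <- base[as.character(aspec$points[1]), ]
    pb <- base[as.character(aspec$points[2]), ]
    u <- (pa - pb) / sqrt(sum((pa - pb)^2))
    cx <- cos(th) * u[1] - sin(th) * u[2]
    cy <- sin(th) * u[1] + cos(th) * u[2]
    moving <- as.character(aspec$points[3])
    xm[, moving] <- pb[1] + .limb_r * cx
    ym[, moving] <- pb[2] + .limb_r * cy
  } else {
    pp <- base[as.character(aspec$points[1]), ]
    moving <- as.character(aspec$points[2])
    xm[, moving] <- pp[1] + .limb_r * sin(th)
    ym[, moving] <- pp[2] + .limb_r * cos(th)
  }
  landmark_series(fps = spec$fps, x = xm, y = ym)
}

#' Generate one synthetic sEMG trial
#'
#' The trial contains `repetition_count` activation bursts (Hann amplitude
#' envelope, 60% duty cycle) over a 20-450 Hz band-limited Gaussian noise
#' carrier, plus an additive powerline sinusoid and Gaussian baseline noise.
#' The burst amplitude is calibrated by passing the unit-amplitude clean
#' burst train once through the conditioning chain and scaling, so that for
#' zero powerline/noise the post-chain overall mean RMS equals
#' `participant_strength` exactly.
#'
#' @param profile A [movement_profile()] (metadata only).
#' @param spec A [cohort_spec()].
#' @param participant_strength Target post-chain mean RMS (mV), > 0.
#' @param repetition_count Number of bursts; must fit in the trial with
#'   nonzero gaps.
#' @param seed Seed for this trial's draws (default `spec$seed`).
#' @return An `emg_recording` with `repetition_markers` set to the true
#'   burst extents.
#' @export
generate_emg <- function(profile, spec, participant_strength,
                         repetition_count = spec$reps_per_condition,
                         seed = spec$seed) {
  stopifnot(inherits(profile, "movement_profile"), inherits(spec, "cohort_spec"))
  if (participant_strength <= 0) stop("participant_strength must be positive")
  fs <- spec$emg_fs
  n <- as.integer(round(spec$trial_duration * fs))
  period <- n / repetition_count
  blen <- as.integer(floor(0.6 * period))
  gap <- period - blen
  if (blen < 8 || gap < 1)
    stop("trial too short to fit ", repetition_count,
         " repetition bursts with nonzero gaps")

  env <- numeric(n)
  starts <- as.integer(round((seq_len(repetition_count) - 1) * period + gap / 2))
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(blen) - 1) / (blen - 1)))
  for (s in starts) env[s + seq_len(blen)] <- hann

  set.seed(seed)
  carrier <- bandpass_filter(stats::rnorm(n), fs, 20, 450)
  carrier <- carrier / sqrt(mean(carrier^2))
  clean <- env * carrier

  # self-calibration: chain response of the unit-amplitude burst train
  m0 <- mean_rms(windowed_rms(bandpass_filter(notch_filter(clean, fs), fs), fs))
  amp <- participant_strength / m0
  tt <- (seq_len(n) - 1) / fs
  sig <- amp * clean +
    spec$powerline_amplitude * sin(2 * pi * spec$powerline_freq * tt) +
    stats::rnorm(n, 0, spec$noise_sd)

  markers <- data.frame(start_s = (starts - 1) / fs,
                        end_s = (starts - 1 + blen) / fs)
  emg_recording(sig, fs = fs,
                movement_id = profile$movement_id, condition = profile$condition,
                repetition_markers = markers)
}

# Correlated (correct, incorrect) strength pair for one participant:
# bivariate normal with the two condition means/SDs and the spec's
# correlation, truncated below at a small positive floor.
.draw_strength_pair <- function(mu_c, sd_c, mu_i, sd_i, rho, floor_mv = 0.005) {
  z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
  s_c <- mu_c + sd_c * z1
  s_i <- mu_i + sd_i * (rho * z1 + sqrt(1 - rho^2) * z2)
  c(correct = max(s_c, floor_mv), incorrect = max(s_i, floor_mv))
}

#' Generate a full synthetic cohort
#'
#' For each participant: one (correct, incorrect) strength pair per movement
#' drawn from a correlated bivariate normal (truncated at 0.005 mV);
#' `reps_per_condition` landmark trials per condition per movement; one sEMG
#' recording per (participant, movement, condition) containing
#' `reps_per_condition` bursts. Fully reproducible from `spec$seed`.
#'
#' @param profiles List of [movement_profile()] objects covering both
#'   conditions of each movement (e.g. from [reference_profiles()]).
#' @param spec A [cohort_spec()].
#' @param components Which data to generate: `"landmarks"`, `"emg"` or both.
#' @param registry Angle registry used for landmark injection.
#' @return An object of class `cbe_cohort` with fields `spec`, `profiles`,
#'   `manifest` (one row per repetition), `landmarks`, `emg`, `strengths`.
#' @export
generate_cohort <- function(profiles, spec,
                            components = c("landmarks", "emg"),
                            registry = default_angle_registry()) {
  stopifnot(inherits(spec, "cohort_spec"))
  components <- match.arg(components, c("landmarks", "emg"), several.ok = TRUE)
  keys <- vapply(profiles, function(p) paste(p$movement_id, p$condition), "")
  if (anyDuplicated(keys))
    stop("duplicate (movement, condition) profile(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  movements <- unique(vapply(profiles, function(p) p$movement_id, ""))
  for (m in movements) {
    conds <- vapply(profiles[vapply(profiles, function(p) p$movement_id, "") == m],
                    function(p) p$condition, "")
    if (!all(c("correct", "incorrect") %in% conds))
      stop("profiles must cover both conditions of movement ", m)
  }
  prof_of <- function(m, cond) {
    profiles[[which(keys == paste(m, cond))]]
  }

  P <- spec$n_participants; R <- spec$reps_per_condition
  strengths <- NULL
  landmarks <- list(); emg <- list()
  rows <- vector("list", P * length(movements) * 2L * R)
  k <- 0L
  for (p in seq_len(P)) {
    pid <- sprintf("P%02d", p)
    for (m in movements) {
      mi <- .movement_index(m)
      pc <- prof_of(m, "correct"); pi_ <- prof_of(m, "incorrect")
      set.seed(sub_seed(spec$seed, 3L, p, mi))
      s <- .draw_strength_pair(pc$emg_mean, pc$emg_sd_between,
                               pi_$emg_mean, pi_$emg_sd_between,
                               spec$strength_correlation)
      strengths <- rbind(strengths, data.frame(
        participant_id = pid, movement_id = m,
        strength_correct = s[["correct"]], strength_incorrect = s[["incorrect"]]))
      for (cond in c("correct", "incorrect")) {
        prof <- prof_of(m, cond)
        ci <- .condition_index(cond)
        emg_key <- paste(pid, m, cond, sep = "_")
        if ("emg" %in% components) {
          rec <- generate_emg(prof, spec, s[[cond]], repetition_count = R,
                              seed = sub_seed(spec$seed, 4L, p, mi, ci))
          rec$participant_id <- pid
          emg[[emg_key]] <- rec
        }
        for (r in seq_len(R)) {
          lm_key <- sprintf("%s_r%02d", emg_key, r)
          if ("landmarks" %in% components) {
            landmarks[[lm_key]] <-
              generate_landmark_series(prof, spec, p, r, registry = registry)
          }
          k <- k + 1L
          rows[[k]] <- data.frame(
            participant_id = pid, movement_id = m, condition = cond,
            repetition = r, landmark_id = lm_key, emg_id = emg_key)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows[seq_len(k)])
  rownames(strengths) <- NULL
  structure(list(spec = spec, profiles = profiles, manifest = manifest,
                 landmarks = landmarks, emg = emg, strengths = strengths,
                 registry = registry),
            class = "cbe_cohort")
}

#' @export
print.cbe_cohort <- function(x, ...) {
  cat("<cbe_cohort> ", x$spec$n_participants, " participants, ",
      length(unique(x$manifest$movement_id)), " movement(s), ",
      nrow(x$manifest), " repetition entries\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one landmark CSV per repetition, one sEMG CSV (and markers CSV) per
#' (participant, movement, condition), and `manifest.csv` listing every
#' trial with participant/movement/condition/repetition keys and file paths.
#'
#' @param cohort A `cbe_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cbe_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$landmark_path <- NA_character_
  man$emg_path <- NA_character_
  for (key in names(cohort$landmarks)) {
    path <- file.path(dir, paste0(key, "_landmarks.csv"))
    write_landmarks(cohort$landmarks[[key]], path)
    man$landmark_path[man$landmark_id == key] <- path
  }
  for (key in names(cohort$emg)) {
    path <- file.path(dir, paste0(key, "_emg.csv"))
    write_emg(cohort$emg[[key]], path)
    mk <- cohort$emg[[key]]$repetition_markers
    if (!is.null(mk)) {
      utils::write.csv(cbind(rep = seq_len(nrow(mk)), mk),
                       file.path(dir, paste0(key, "_markers.csv")),
                       row.names = FALSE, quote = FALSE)
    }
    man$emg_path[man$emg_id == key] <- path
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
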