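# Cohort-level aggregation and paired correct-vs-incorrect statistics:
# per-participant means, condition summaries (cohort mean +/- SD), paired
# t-tests with Holm-adjusted companions, and the tidy tables behind the
# scatter and boxplot comparisons.

#' Per-participant mean angle and mean sEMG RMS
#'
#' One row per (participant, movement, condition): the mean over repetitions
#' of the per-repetition mean scored angle, and the overall mean RMS of the
#' condition's sEMG recording after the full conditioning chain.
#'
#' @param cohort A `cbe_cohort`.
#' @param what Components to summarise: `"angle"`, `"emg"` or both
#'   (restricted to what the cohort contains).
#' @return data.frame with columns `participant_id`, `movement_id`,
#'   `condition`, and `mean_angle_deg` / `mean_rms_mv` as requested.
#' @export
per_participant_means <- function(cohort, what = c("angle", "emg")) {
  stopifnot(inherits(cohort, "cbe_cohort"))
  what <- match.arg(what, c("angle", "emg"), several.ok = TRUE)
  if ("angle" %in% what && !length(cohort$landmarks))
    stop("cohort holds no landmark data")
  if ("emg" %in% what && !length(cohort$emg))
    stop("cohort holds no sEMG data")
  man <- cohort$manifest
  prof_angle <- vapply(cohort$profiles, function(p) p$angle_name, "")
  names(prof_angle) <- vapply(cohort$profiles, function(p) paste(p$movement_id, p$condition), "")
  groups <- unique(man[, c("participant_id", "movement_id", "condition")])
  # completeness: both conditions per participant per movement
  for (p in unique(groups$participant_id)) {
    for (m in unique(groups$movement_id)) {
      conds <- groups$condition[groups$participant_id == p & groups$movement_id == m]
      miss <- setdiff(c("correct", "incorrect"), conds)
      if (length(miss))
        stop("participant ", p, " is missing condition '", miss[1],
             "' for movement ", m)
    }
  }
  emg_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- man[man$participant_id == g$participant_id &
                 man$movement_id == g$movement_id &
                 man$condition == g$condition, ]
    out <- g
    if ("angle" %in% what) {
      aspec <- cohort$registry[[prof_angle[[paste(g$movement_id, g$condition)]]]]
      rep_means <- vapply(sub$landmark_id, function(key) {
        mean_angle(compute_angle_series(cohort$landmarks[[key]], aspec))
      }, numeric(1))
      out$mean_angle_deg <- mean(rep_means)
    }
    if ("emg" %in% what) {
      key <- sub$emg_id[1]
      if (is.null(emg_cache[[key]]))
        emg_cache[[key]] <- mean_rms(emg_envelope(cohort$emg[[key]]))
      out$mean_rms_mv <- emg_cache[[key]]
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Condition summaries (cohort mean +/- SD)
#'
#' Across-participant mean and sample SD (denominator n-1) of the
#' per-participant means, per movement and condition — the shape of the
#' published aggregate table.
#'
#' @param ppm Output of [per_participant_means()].
#' @return data.frame with `movement_id`, `condition`, `n_participants` and
#'   `angle_mean`/`angle_sd`, `emg_mean`/`emg_sd` for the available columns.
#' @export
summarize_conditions <- function(ppm) {
  groups <- unique(ppm[, c("movement_id", "condition")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- ppm[ppm$movement_id == g$movement_id & ppm$condition == g$condition, ]
    if (nrow(sub) < 2) stop("need >= 2 participants per condition")
    out <- data.frame(movement_id = g$movement_id, condition = g$condition,
                      n_participants = nrow(sub))
    if ("mean_angle_deg" %in% names(sub)) {
      out$angle_mean <- mean(sub$mean_angle_deg)
      out$angle_sd <- stats::sd(sub$mean_angle_deg)
    }
    if ("mean_rms_mv" %in% names(sub)) {
      out$emg_mean <- mean(sub$mean_rms_mv)
      out$emg_sd <- stats::sd(sub$mean_rms_mv)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Paired t-test between conditions
#'
#' Two-sided paired t-test on `correct - incorrect` differences, paired by
#' participant. The degenerate all-differences-zero case (identical
#' vectors) returns t = 0, p = 1; zero-variance differences with a nonzero
#' mean are an error.
#'
#' @param correct,incorrect Equal-length numeric vectors (length >= 2),
#'   ordered by participant.
#' @return An object of class `paired_ttest`: `t_stat`, `df`, `p_value`,
#'   `mean_diff`, `n_pairs`.
#' @export
paired_ttest <- function(correct, incorrect) {
  if (length(correct) != length(incorrect)) stop("length mismatch between conditions")
  n <- length(correct)
  if (n < 2) stop("need at least 2 pairs")
  d <- correct - incorrect
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      res <- list(t_stat = 0, df = n - 1, p_value = 1, mean_diff = 0, n_pairs = n)
      class(res) <- "paired_ttest"
      return(res)
    }
    stop("zero-variance differences with nonzero mean: t-statistic undefined")
  }
  tt <- stats::t.test(correct, incorrect, paired = TRUE)
  structure(list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = unname(tt$estimate),
                 n_pairs = n),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.3g, mean diff = %.4g (n = %d)\n",
              x$t_stat, x$df, x$p_value, x$mean_diff, x$n_pairs))
  invisible(x)
}

#' Paired tests for every movement in a cohort
#'
#' Per movement, the paired t-test across participants on the chosen
#' per-participant summary. Raw p-values are reported alongside
#' Holm-adjusted ones (the adjustment is an additive output; the published
#' comparisons are raw).
#'
#' @param ppm Output of [per_participant_means()].
#' @param value `"emg"` (mean RMS, default) or `"angle"` (mean angle).
#' @return data.frame with one row per movement: `t_stat`, `df`, `p_value`,
#'   `p_holm`, `mean_diff`, `n_pairs`.
#' @export
movement_ttests <- function(ppm, value = c("emg", "angle")) {
  value <- match.arg(value)
  col <- if (value == "emg") "mean_rms_mv" else "mean_angle_deg"
  if (!col %in% names(ppm)) stop("column ", col, " absent from per-participant table")
  movements <- unique(ppm$movement_id)
  rows <- lapply(movements, function(m) {
    sub <- ppm[ppm$movement_id == m, ]
    sub <- sub[order(sub$participant_id), ]
    cor_ <- sub[[col]][sub$condition == "correct"]
    inc <- sub[[col]][sub$condition == "incorrect"]
    tt <- paired_ttest(cor_, inc)
    data.frame(movement_id = m, t_stat = tt$t_stat, df = tt$df,
               p_value = tt$p_value, mean_diff = tt$mean_diff,
               n_pairs = tt$n_pairs)
  })
  res <- do.call(rbind, rows)
  res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  rownames(res) <- NULL
  res
}

#' Per-participant scatter table for one movement
#'
#' One row per participant with the correct-condition mean on x and the
#' incorrect-condition mean on y, flagging points below the identity line
#' (incorrect < correct), the pattern indicating stronger activation under
#' correct execution.
#'
#' @param ppm Output of [per_participant_means()] including sEMG.
#' @param movement Movement identifier.
#' @return data.frame with `participant_id`, `correct_mean_mv`,
#'   `incorrect_mean_mv`, `below_identity`.
#' @export
scatter_table <- function(ppm, movement) {
  if (!"mean_rms_mv" %in% names(ppm)) stop("per-participant table lacks sEMG means")
  sub <- ppm[ppm$movement_id == movement, ]
  if (!nrow(sub)) stop("movement ", movement, " absent from table")
  sub <- sub[order(sub$participant_id), ]
  cor_ <- sub[sub$condition == "correct", ]
  inc <- sub[sub$condition == "incorrect", ]
  data.frame(participant_id = cor_$participant_id,
             correct_mean_mv = cor_$mean_rms_mv,
             incorrect_mean_mv = inc$mean_rms_mv,
             below_identity = inc$mean_rms_mv < cor_$mean_rms_mv)
}

#' Tidy per-repetition peak table with quartiles
#'
#' @param peaks Named list mapping condition to the numeric vector of
#'   per-repetition peak RMS values (mV).
#' @return List with `peaks` (tidy rows `condition`, `repetition`,
#'   `peak_mv`) and `summary` (per condition: `q1`, `median`, `q3`, `iqr`;
#'   linear-interpolation quantile convention).
#' @export
boxplot_table <- function(peaks) {
  if (!length(peaks) || is.null(names(peaks))) stop("peaks must be a named list")
  tidy <- do.call(rbind, lapply(names(peaks), function(cond) {
    v <- peaks[[cond]]
    if (!length(v)) stop("condition ", cond, " has no repetitions")
    data.frame(condition = cond, repetition = seq_along(v), peak_mv = v)
  }))
  summ <- do.call(rbind, lapply(names(peaks), function(cond) {
    q <- stats::quantile(peaks[[cond]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(condition = cond, q1 = q[1], median = q[2], q3 = q[3],
               iqr = q[3] - q[1])
  }))
  list(peaks = tidy, summary = summ)
}
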