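# Windowed time- and frequency-domain features from joint-angle series:
# 30-frame (1 s) windows with 50% overlap; five descriptive statistics plus
# five Welch-PSD features over the 1-20 Hz band (clipped to what the frame
# rate can represent).

#' Sliding-window specification
#'
#' @param size_frames Window length in frames (>= 2), default 30 (1 s at
#'   30 fps).
#' @param hop_frames Hop in frames, `0 < hop <= size`; default 15 (50%
#'   overlap).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(size_frames = 30, hop_frames = 15) {
  size_frames <- as.integer(size_frames); hop_frames <- as.integer(hop_frames)
  if (size_frames < 2) stop("window size must be >= 2 frames")
  if (hop_frames < 1 || hop_frames > size_frames)
    stop("hop must satisfy 0 < hop <= size")
  structure(list(size_frames = size_frames, hop_frames = hop_frames),
            class = "window_spec")
}

#' Split an angle series into sliding windows
#'
#' Windows start at offsets 0, hop, 2*hop, ...; the count is
#' `floor((N - size) / hop) + 1`; a trailing partial window is dropped.
#'
#' @param series An `angle_series` (or numeric vector).
#' @param spec A [window_spec()].
#' @return List of numeric windows.
#' @export
sliding_windows <- function(series, spec = window_spec()) {
  vals <- if (inherits(series, "angle_series")) series$values else as.numeric(series)
  n <- length(vals)
  if (n < spec$size_frames)
    stop("series length ", n, " shorter than one window (",
         spec$size_frames, " frames)")
  starts <- seq(1L, n - spec$size_frames + 1L, by = spec$hop_frames)
  lapply(starts, function(s) vals[s:(s + spec$size_frames - 1L)])
}

#' Time-domain window features
#'
#' Mean, minimum, maximum, median and SD of the window. The SD uses the
#' population convention (denominator n), applied consistently with the
#' spectral SD.
#'
#' @param window Non-empty numeric vector.
#' @return Named numeric vector `mean`, `minimum`, `maximum`, `median`, `sd`.
#' @export
time_features <- function(window) {
  if (!length(window)) stop("empty window")
  m <- mean(window)
  c(mean = m, minimum = min(window), maximum = max(window),
    median = stats::median(window), sd = sqrt(mean((window - m)^2)))
}

# One-sided Welch PSD of a single mean-detrended, Hann-tapered segment
# (the 30-sample windows admit no sub-segmenting worth its resolution loss).
# Density scaling matches the usual Welch convention: power/Hz, interior
# bins doubled.
welch_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  xw <- (x - mean(x)) * w
  nb <- floor(n / 2) + 1L
  p <- (Mod(stats::fft(xw))^2)[seq_len(nb)] * 2 / (fs * sum(w^2))
  p[1] <- p[1] / 2
  if (n %% 2 == 0) p[nb] <- p[nb] / 2
  list(freq = (seq_len(nb) - 1) * fs / n, psd = p)
}

#' Frequency-domain window features
#'
#' Welch PSD of the window (single Hann-tapered, mean-detrended segment);
#' features over the in-band bins of `band` clipped to `[band[1], fps/2)`:
#' mean, peak and minimum power, SD of power (population convention), and
#' the median frequency (smallest in-band frequency at which cumulative
#' in-band power reaches half the total).
#'
#' @param window Numeric vector, length >= 8.
#' @param fps Sampling rate of the angle series (Hz), > 2.
#' @param band Analysis band in Hz, default `c(1, 20)`.
#' @param warn_clip Warn when the band is clipped at Nyquist.
#' @return Named numeric vector `psd_mean`, `psd_peak`, `psd_min`,
#'   `median_freq`, `psd_sd`.
#' @export
spectral_features <- function(window, fps, band = c(1, 20), warn_clip = TRUE) {
  if (length(window) < 8) stop("window too short for spectral features (need >= 8)")
  if (fps <= 2) stop("fps must exceed 2 Hz")
  hi <- band[2]
  if (hi >= fps / 2) {
    if (warn_clip)
      warning("analysis band [", band[1], ", ", band[2], "] Hz clipped to [",
              band[1], ", ", fps / 2, ") by the Nyquist frequency")
    hi <- fps / 2
  }
  ps <- welch_psd(window, fps)
  sel <- ps$freq >= band[1] & ps$freq < hi
  if (!any(sel)) stop("empty analysis band after Nyquist clipping")
  p <- ps$psd[sel]; f <- ps$freq[sel]
  tot <- sum(p)
  mf <- if (tot > 0) f[which(cumsum(p) >= tot / 2)[1]] else f[1]
  m <- mean(p)
  c(psd_mean = m, psd_peak = max(p), psd_min = min(p),
    median_freq = mf, psd_sd = sqrt(mean((p - m)^2)))
}

#' Names of the ten feature columns
#' @return Character vector in stable column order.
#' @export
feature_columns <- function() {
  c("mean", "minimum", "maximum", "median", "sd",
    "psd_mean", "psd_peak", "psd_min", "median_freq", "psd_sd")
}

#' Build the windowed feature table for a cohort
#'
#' One row per (repetition trial, angle, window) with the ten features, the
#' trial keys and a binary label (correct = 1, incorrect = 0). Row order is
#' deterministic: manifest order, then window index. By default each
#' movement is scored on its profile's angle; pass `angles` to override.
#'
#' @param cohort A `cbe_cohort`, or a manifest data.frame with a
#'   `landmark_path` column resolvable to landmark CSVs (plus
#'   participant/movement/condition/repetition keys).
#' @param angles Character vector of registry angle names; default the
#'   profile angle of each movement (cohort input) or all registry angles
#'   (manifest input).
#' @param registry Angle registry.
#' @param window A [window_spec()].
#' @param band Spectral analysis band (Hz).
#' @return data.frame of class `feature_table`.
#' @export
build_feature_table <- function(cohort, angles = NULL,
                                registry = default_angle_registry(),
                                window = window_spec(), band = c(1, 20)) {
  if (inherits(cohort, "cbe_cohort")) {
    manifest <- cohort$manifest
    get_series <- function(row) cohort$landmarks[[row$landmark_id]]
    prof_angle <- vapply(cohort$profiles, function(p) p$angle_name, "")
    names(prof_angle) <- vapply(cohort$profiles, function(p) p$movement_id, "")
    angle_for <- function(m) if (is.null(angles)) unique(prof_angle[names(prof_angle) == m]) else angles
    fps <- cohort$spec$fps
  } else {
    manifest <- cohort
    if (!"landmark_path" %in% names(manifest))
      stop("manifest input needs a landmark_path column")
    get_series <- function(row) {
      if (!file.exists(row$landmark_path))
        stop("unreadable trial: ", row$landmark_path)
      read_landmarks(row$landmark_path)
    }
    angle_for <- function(m) if (is.null(angles)) names(registry) else angles
    fps <- NULL
  }
  clipped_warned <- FALSE
  chunks <- list()
  k <- 0L
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    series <- get_series(row)
    for (aname in angle_for(row$movement_id)) {
      aspec <- registry[[aname]]
      if (is.null(aspec)) stop("angle '", aname, "' not in registry")
      ang <- compute_angle_series(series, aspec)
      wins <- sliding_windows(ang, window)
      feats <- t(vapply(seq_along(wins), function(j) {
        tf <- time_features(wins[[j]])
        sf <- withCallingHandlers(
          spectral_features(wins[[j]], ang$fps, band = band,
                            warn_clip = !clipped_warned),
          warning = function(w) {
            clipped_warned <<- TRUE
            invokeRestart("muffleWarning")
          })
        c(tf, sf)
      }, numeric(10)))
      df <- data.frame(
        participant_id = row$participant_id, movement_id = row$movement_id,
        condition = row$condition, repetition = row$repetition,
        window_index = seq_len(nrow(feats)), angle_name = aname)
      df <- cbind(df, as.data.frame(feats))
      k <- k + 1L
      chunks[[k]] <- df
    }
  }
  tbl <- do.call(rbind, chunks)
  tbl$label <- as.integer(tbl$condition == "correct")
  rownames(tbl) <- NULL
  if (anyNA(tbl[feature_columns()])) stop("feature table contains missing values")
  class(tbl) <- c("feature_table", "data.frame")
  tbl
}

#' Write / read a feature table CSV (lossless round trip)
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `path` invisibly (write); a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tbl) <- c("feature_table", "data.frame")
  tbl
}
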