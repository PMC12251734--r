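# Surface-EMG conditioning chain: 50 Hz notch -> 20-450 Hz Butterworth
# bandpass -> windowed RMS envelope, with the normalised/smoothed variant
# used for visual comparison and per-repetition summaries. All filters are
# applied zero-phase (forward-backward) with odd-extension edge padding.

#' Construct an sEMG recording
#'
#' @param signal Numeric signal in mV.
#' @param fs Sampling rate (Hz), > 0.
#' @param muscle,participant_id,movement_id,condition Optional metadata labels.
#' @param repetition_markers Optional data.frame with columns `start_s`,
#'   `end_s` (one row per repetition), ordered and non-overlapping.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, fs, muscle = NA_character_,
                          participant_id = NA_character_,
                          movement_id = NA_character_,
                          condition = NA_character_,
                          repetition_markers = NULL) {
  if (fs <= 0) stop("fs must be positive")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (!is.null(repetition_markers)) {
    m <- repetition_markers
    if (!all(c("start_s", "end_s") %in% names(m)))
      stop("repetition_markers needs columns start_s, end_s")
    if (any(m$end_s <= m$start_s)) stop("repetition markers must have end_s > start_s")
    if (is.unsorted(m$start_s) || any(utils::head(m$end_s, -1) > utils::tail(m$start_s, -1)))
      stop("repetition markers must be ordered and non-overlapping")
  }
  structure(list(signal = as.numeric(signal), fs = fs, muscle = muscle,
                 participant_id = participant_id, movement_id = movement_id,
                 condition = condition, repetition_markers = repetition_markers),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat("<emg_recording> ", length(x$signal), " samples @ ", x$fs, " Hz (",
      round(length(x$signal) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' Read / write sEMG CSV (`time_s,value_mv`)
#'
#' @param path CSV path.
#' @param ... Metadata passed on to [emg_recording()].
#' @return An `emg_recording` (read) or `path` invisibly (write).
#' @export
read_emg <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value_mv") %in% names(df)))
    stop("malformed sEMG CSV (need columns time_s,value_mv): ", path)
  if (nrow(df) < 2) stop("sEMG file too short: ", path)
  fs <- 1 / stats::median(diff(df$time_s))
  emg_recording(df$value_mv, fs = round(fs), ...)
}

#' @rdname read_emg
#' @param rec An `emg_recording`.
#' @export
write_emg <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- length(rec$signal)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / rec$fs, value_mv = rec$signal),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Zero-phase filtering with odd-extension padding at both ends (the plain
# reverse-filter-reverse scheme leaves edge transients large enough to break
# the stopband contracts on short records).
filtfilt_pad <- function(b, a, x, padlen = 250L) {
  n <- length(x)
  p <- min(padlen, n - 1L)
  if (p < 1) stop("signal too short to filter")
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Powerline notch filter
#'
#' Second-order IIR notch (quality factor `q`) applied zero-phase, removing
#' narrowband powerline interference while leaving neighbouring frequencies
#' essentially untouched.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param f0 Notch frequency (Hz), default 50; must be below `fs/2`.
#' @param q Quality factor (centre frequency / -3 dB bandwidth).
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, fs, f0 = 50, q = 30) {
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist (fs/2)")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  filtfilt_pad(b, a, x)
}

#' Butterworth bandpass filter
#'
#' Order-4 Butterworth bandpass applied zero-phase (effective order 8),
#' removing low-frequency motion artefact and high-frequency noise.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges (Hz), `0 < lo < hi < fs/2`.
#' @param order Butterworth order per pass.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, lo = 20, hi = 450, order = 4) {
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2")
  bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  filtfilt_pad(bt$b, bt$a, x)
}

#' Windowed RMS envelope
#'
#' Root-mean-square over sliding windows (default 100 ms, 50% overlap).
#' The window count is `floor((N - W) / H) + 1` with `W` window samples and
#' `H` hop samples; trailing samples that do not fill a window are dropped.
#'
#' @param x Numeric signal (mV).
#' @param fs Sampling rate (Hz).
#' @param window_ms Window length in milliseconds.
#' @param overlap Fractional overlap in [0, 1).
#' @return An object of class `rms_envelope` with fields `values`,
#'   `window_start_s`, `window_ms`, `overlap`, `hop_s`.
#' @export
windowed_rms <- function(x, fs, window_ms = 100, overlap = 0.5) {
  w <- as.integer(round(fs * window_ms / 1000))
  if (w < 1) stop("window shorter than one sample")
  if (length(x) < w) stop("signal shorter than one window (", w, " samples)")
  h <- max(1L, as.integer(round(w * (1 - overlap))))
  starts <- seq(1L, length(x) - w + 1L, by = h)
  cs <- c(0, cumsum(x^2))
  vals <- sqrt((cs[starts + w] - cs[starts]) / w)
  structure(list(values = vals, window_start_s = (starts - 1) / fs,
                 window_ms = window_ms, overlap = overlap,
                 window_s = w / fs, hop_s = h / fs, fs = fs),
            class = "rms_envelope")
}

#' @export
print.rms_envelope <- function(x, ...) {
  cat("<rms_envelope> ", length(x$values), " windows (", x$window_ms,
      " ms, ", x$overlap * 100, "% overlap)\n", sep = "")
  invisible(x)
}

#' Normalise and resample an envelope to 500 points
#'
#' Maps window indices affinely onto [0, 1] and linearly interpolates the
#' envelope onto `n_points` equally spaced query points, so trials of
#' different durations share a common time base. Endpoints are preserved.
#'
#' @param env An `rms_envelope` with at least 2 windows.
#' @param n_points Number of resampled points (default 500).
#' @return List with `values` (length `n_points`) and `time_norm`.
#' @export
normalize_resample <- function(env, n_points = 500) {
  stopifnot(inherits(env, "rms_envelope"))
  n <- length(env$values)
  if (n < 2) stop("need at least 2 windows to resample")
  tq <- seq(0, 1, length.out = n_points)
  out <- stats::approx(x = seq(0, 1, length.out = n), y = env$values,
                       xout = tq)$y
  list(values = out, time_norm = tq)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Convolution with a unit-area Gaussian kernel (`sigma` in samples,
#' truncated at 4 sigma), reflective padding, output length equals input
#' length. Used to smooth normalised envelopes for visual comparison and to
#' stabilise repetition segmentation.
#'
#' @param x Numeric vector.
#' @param sigma Kernel SD in samples, > 0.
#' @return Smoothed vector.
#' @export
gaussian_smooth <- function(x, sigma = 10) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!length(x)) stop("empty input")
  r <- as.integer(ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  idx <- c(pmin(n, rev(seq_len(r)) + 1L), seq_len(n), pmax(1L, n - seq_len(r)))
  xp <- x[idx]
  y <- as.numeric(stats::filter(xp, k, sides = 2))
  y[(r + 1):(r + n)]
}

#' Mean of an RMS envelope
#'
#' The overall average RMS across the trial, the scalar summary of muscle
#' activation intensity.
#'
#' @param env An `rms_envelope`.
#' @return Mean envelope value (mV).
#' @export
mean_rms <- function(env) {
  stopifnot(inherits(env, "rms_envelope"))
  if (!length(env$values)) stop("empty envelope")
  mean(env$values)
}

#' Segment an envelope into repetition bursts
#'
#' If explicit `markers` (seconds) are supplied they take precedence and are
#' converted to window indices. Otherwise threshold-crossing detection is
#' used: the envelope is Gaussian-smoothed (sigma = 5 windows), thresholded
#' at the midpoint of its 10th and 90th percentiles, runs separated by gaps
#' shorter than 0.25 s are merged, and runs shorter than 0.25 s are dropped.
#'
#' @param env An `rms_envelope`.
#' @param expected Expected number of repetitions; if not `NULL` and the
#'   detected count differs, an error of class `cbeqc_segment_count_error`
#'   carrying the detected count (`$detected`) is thrown.
#' @param markers Optional data.frame with `start_s`, `end_s`.
#' @return data.frame with columns `start_window`, `end_window` (1-based,
#'   inclusive), ordered and disjoint.
#' @export
segment_repetitions <- function(env, expected = 10, markers = NULL) {
  stopifnot(inherits(env, "rms_envelope"))
  nw <- length(env$values)
  if (!nw) stop("empty envelope")
  centers <- env$window_start_s + env$window_s / 2
  if (!is.null(markers)) {
    segs <- do.call(rbind, lapply(seq_len(nrow(markers)), function(i) {
      idx <- which(centers >= markers$start_s[i] & centers <= markers$end_s[i])
      if (!length(idx)) return(NULL)
      data.frame(start_window = min(idx), end_window = max(idx))
    }))
    if (is.null(segs)) segs <- data.frame(start_window = integer(), end_window = integer())
    return(segs)
  }
  sm <- gaussian_smooth(env$values, sigma = 5)
  thr <- mean(stats::quantile(sm, c(0.1, 0.9), names = FALSE))
  above <- sm > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(start_window = starts[r$values], end_window = ends[r$values])
  min_windows <- max(1L, ceiling(0.25 / env$hop_s))
  # merge short gaps
  if (nrow(segs) > 1) {
    keep <- segs[1, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      gap <- segs$start_window[i] - keep$end_window[nrow(keep)] - 1L
      if (gap < min_windows) {
        keep$end_window[nrow(keep)] <- segs$end_window[i]
      } else {
        keep <- rbind(keep, segs[i, ])
      }
    }
    segs <- keep
  }
  segs <- segs[segs$end_window - segs$start_window + 1L >= min_windows, , drop = FALSE]
  rownames(segs) <- NULL
  if (!is.null(expected) && nrow(segs) != expected) {
    cond <- structure(
      class = c("cbeqc_segment_count_error", "error", "condition"),
      list(message = paste0("detected ", nrow(segs), " repetition segment(s), expected ",
                            expected),
           call = sys.call(-1), detected = nrow(segs), segments = segs))
    stop(cond)
  }
  segs
}

#' Peak RMS per repetition segment
#'
#' @param env An `rms_envelope`.
#' @param segs Segmentation as returned by [segment_repetitions()].
#' @return Numeric vector, one peak (mV) per segment.
#' @export
peak_rms_per_repetition <- function(env, segs) {
  stopifnot(inherits(env, "rms_envelope"))
  nw <- length(env$values)
  if (any(segs$start_window < 1 | segs$end_window > nw |
            segs$start_window > segs$end_window))
    stop("segment out of envelope range")
  vapply(seq_len(nrow(segs)), function(i) {
    max(env$values[segs$start_window[i]:segs$end_window[i]])
  }, numeric(1))
}

#' Full sEMG conditioning chain
#'
#' notch -> bandpass -> windowed RMS. Summaries (mean RMS, per-repetition
#' peaks) are computed on this un-normalised envelope; the normalised,
#' smoothed 500-point variant is for visual comparison only.
#'
#' @param rec An `emg_recording`.
#' @param f0 Notch frequency (Hz).
#' @param lo,hi Bandpass edges (Hz).
#' @param window_ms,overlap RMS window parameters.
#' @return An `rms_envelope`.
#' @export
emg_envelope <- function(rec, f0 = 50, lo = 20, hi = 450,
                         window_ms = 100, overlap = 0.5) {
  stopifnot(inherits(rec, "emg_recording"))
  y <- notch_filter(rec$signal, rec$fs, f0 = f0)
  y <- bandpass_filter(y, rec$fs, lo = lo, hi = hi)
  windowed_rms(y, rec$fs, window_ms = window_ms, overlap = overlap)
}

#' Per-trial sEMG summary
#'
#' Runs the conditioning chain and summarises the trial: overall mean RMS,
#' repetition segmentation (markers take precedence when the recording
#' carries them) and per-repetition peak RMS.
#'
#' @param rec An `emg_recording`.
#' @param expected_reps Expected repetition count for detection-based
#'   segmentation; ignored when markers exist. `NULL` skips the count check.
#' @param ... Passed to [emg_envelope()].
#' @return List with `envelope`, `mean_rms`, `segments`, `peak_rms`.
#' @export
emg_summary <- function(rec, expected_reps = NULL, ...) {
  env <- emg_envelope(rec, ...)
  segs <- segment_repetitions(env, expected = expected_reps,
                              markers = rec$repetition_markers)
  list(envelope = env, mean_rms = mean_rms(env), segments = segs,
       peak_rms = peak_rms_per_repetition(env, segs))
}
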