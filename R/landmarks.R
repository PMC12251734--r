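# MediaPipe-layout pose landmark handling. The eight lower-body keypoints:
# 11/12 shoulders, 23/24 hips, 25/26 knees, 27/28 ankles. Coordinates are
# normalised image coordinates, origin top-left, y increasing downward.

#' Landmark IDs required by the kinematic analysis
#' @return Integer vector of the eight MediaPipe landmark IDs.
#' @export
required_landmarks <- function() c(11L, 12L, 23L, 24L, 25L, 26L, 27L, 28L)

#' Construct a landmark series
#'
#' @param fps Frame rate in Hz (> 0).
#' @param x,y Numeric matrices, one row per frame, one column per landmark;
#'   columns named by landmark ID. All eight [required_landmarks()] must be
#'   present and all coordinates finite.
#' @return An object of class `landmark_series`.
#' @export
landmark_series <- function(fps, x, y) {
  if (fps <= 0) stop("fps must be positive")
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical dimensions")
  req <- as.character(required_landmarks())
  missing_ids <- setdiff(req, colnames(x))
  if (length(missing_ids))
    stop("missing required landmark ID(s): ", paste(missing_ids, collapse = ", "))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("landmark coordinates must be finite")
  structure(list(fps = fps, x = x, y = y, n_frames = nrow(x)),
            class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  cat("<landmark_series> ", x$n_frames, " frames @ ", x$fps, " fps, ",
      ncol(x$x), " landmarks\n", sep = "")
  invisible(x)
}

#' Read a landmark CSV
#'
#' Expects the long dialect `frame,landmark_id,x,y` with 0-based contiguous
#' frames, one row per landmark per frame. Coordinates must lie within
#' [-0.5, 1.5] (tolerance for slightly off-screen pose estimates).
#'
#' @param path CSV file path.
#' @param fps Frame rate to attach (Hz); the file stores frames only.
#' @return A `landmark_series`.
#' @export
read_landmarks <- function(path, fps = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "landmark_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("malformed landmark CSV (need columns frame,landmark_id,x,y): ", path)
  if (!nrow(df)) stop("empty landmark file: ", path)
  frames <- sort(unique(df$frame))
  if (!identical(frames, seq(0L, max(frames))) || frames[1] != 0L)
    stop("frames must be contiguous and 0-based in ", path)
  bad <- !is.finite(df$x) | !is.finite(df$y) |
    df$x < -0.5 | df$x > 1.5 | df$y < -0.5 | df$y > 1.5
  if (any(bad))
    stop("coordinates outside [-0.5, 1.5] at frame(s) ",
         paste(utils::head(unique(df$frame[bad]), 5), collapse = ", "),
         " in ", path)
  n <- length(frames)
  req <- required_landmarks()
  xm <- matrix(NA_real_, n, length(req), dimnames = list(NULL, as.character(req)))
  ym <- xm
  for (id in req) {
    sub <- df[df$landmark_id == id, ]
    if (nrow(sub) != n) {
      have <- unique(sub$frame)
      miss <- setdiff(frames, have)
      stop("landmark ID ", id, " missing at frame(s) ",
           paste(utils::head(miss, 5), collapse = ", "), " in ", path)
    }
    ord <- order(sub$frame)
    xm[, as.character(id)] <- sub$x[ord]
    ym[, as.character(id)] <- sub$y[ord]
  }
  landmark_series(fps = fps, x = xm, y = ym)
}

#' Write a landmark series to CSV
#'
#' Inverse of [read_landmarks()]; emits the `frame,landmark_id,x,y` dialect.
#'
#' @param series A `landmark_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(series, path) {
  stopifnot(inherits(series, "landmark_series"))
  ids <- as.integer(colnames(series$x))
  n <- series$n_frames
  df <- data.frame(
    frame = rep(seq_len(n) - 1L, times = length(ids)),
    landmark_id = rep(ids, each = n),
    x = as.vector(series$x),
    y = as.vector(series$y)
  )
  df <- df[order(df$frame, df$landmark_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Coordinates of one landmark across frames, as an n x 2 matrix.
landmark_xy <- function(series, id) {
  key <- as.character(id)
  if (!key %in% colnames(series$x)) stop("landmark ID ", id, " not present")
  cbind(series$x[, key], series$y[, key])
}
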