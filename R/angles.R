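# Vector-based joint-angle geometry on 2D pose landmarks. All angles are in
# degrees; cosines are clamped to [-1, 1] before arccos so collinear points
# are safe under floating point.

.rad2deg <- 180 / pi

#' Vertex angle at the middle point of a three-point chain
#'
#' Angle at vertex `b` between rays `b->a` and `b->c`, in [0, 180] degrees.
#' Symmetric in `a` and `c`; invariant to translation, rotation and uniform
#' scaling of the three points.
#'
#' @param a,b,c Numeric length-2 points (x, y).
#' @return Angle in degrees.
#' @export
vertex_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length ray at vertex")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * .rad2deg
}

#' Inclination of a body segment from the image vertical
#'
#' Unsigned angle in [0, 180] degrees between the directed segment `p->q`
#' and the downward image-vertical axis (y increases downward, so a segment
#' pointing straight down scores 0 and straight up scores 180). Swapping
#' `p` and `q` maps the angle to its 180-degree complement.
#'
#' @param p,q Numeric length-2 points (x, y).
#' @return Angle in degrees.
#' @export
segment_inclination <- function(p, q) {
  d <- q - p
  n <- sqrt(sum(d^2))
  if (n == 0) stop("coincident points: segment has zero length")
  acos(min(1, max(-1, d[2] / n))) * .rad2deg
}

#' Define a named angle over landmark IDs
#'
#' @param name Angle identifier.
#' @param kind `"vertex"` (three points, angle at the middle one) or
#'   `"inclination"` (two points, angle from image vertical).
#' @param points Ordered landmark IDs: 3 for vertex, 2 for inclination,
#'   drawn from [required_landmarks()], distinct.
#' @param side `"left"` or `"right"`.
#' @return An object of class `angle_spec`.
#' @export
angle_spec <- function(name, kind = c("vertex", "inclination"), points, side) {
  kind <- match.arg(kind)
  side <- match.arg(side, c("left", "right"))
  points <- as.integer(points)
  n_need <- if (kind == "vertex") 3L else 2L
  if (length(points) != n_need)
    stop(kind, " angle needs ", n_need, " landmark IDs")
  if (anyDuplicated(points)) stop("angle points must be distinct")
  bad <- setdiff(points, required_landmarks())
  if (length(bad)) stop("unsupported landmark ID(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, kind = kind, points = points, side = side),
            class = "angle_spec")
}

#' Default six-angle registry
#'
#' Left/right shoulder-hip-knee (vertex at the hip), left/right
#' hip-knee-ankle (vertex at the knee), and left/right knee-ankle segment
#' inclination. The set is configurable: any named list of [angle_spec()]
#' objects can replace it wherever a registry argument is accepted.
#'
#' @return Named list of six `angle_spec` objects.
#' @export
default_angle_registry <- function() {
  list(
    left_hip = angle_spec("left_hip", "vertex", c(11, 23, 25), "left"),
    right_hip = angle_spec("right_hip", "vertex", c(12, 24, 26), "right"),
    left_knee = angle_spec("left_knee", "vertex", c(23, 25, 27), "left"),
    right_knee = angle_spec("right_knee", "vertex", c(24, 26, 28), "right"),
    left_knee_ankle = angle_spec("left_knee_ankle", "inclination", c(25, 27), "left"),
    right_knee_ankle = angle_spec("right_knee_ankle", "inclination", c(26, 28), "right")
  )
}

#' Construct an angle series
#'
#' @param name Angle identifier.
#' @param fps Frame rate (Hz).
#' @param values Angle per frame, degrees, finite, in [0, 180].
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(name, fps, values) {
  if (fps <= 0) stop("fps must be positive")
  if (!all(is.finite(values))) stop("angle values must be finite")
  if (any(values < 0 | values > 180)) stop("angle values must lie in [0, 180]")
  structure(list(name = name, fps = fps, values = as.numeric(values)),
            class = "angle_series")
}

#' Compute a named angle for every frame of a landmark series
#'
#' @param series A `landmark_series`.
#' @param spec An `angle_spec`.
#' @return An `angle_series` of the same length as the input, with `name`
#'   and `fps` propagated.
#' @export
compute_angle_series <- function(series, spec) {
  stopifnot(inherits(series, "landmark_series"), inherits(spec, "angle_spec"))
  if (spec$kind == "vertex") {
    pa <- landmark_xy(series, spec$points[1])
    pb <- landmark_xy(series, spec$points[2])
    pc <- landmark_xy(series, spec$points[3])
    v1 <- pa - pb; v2 <- pc - pb
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    zero <- which(n1 == 0 | n2 == 0)
    if (length(zero))
      stop("zero-length ray at frame ", zero[1] - 1, " for angle ", spec$name)
    cosang <- rowSums(v1 * v2) / (n1 * n2)
    vals <- acos(pmin(1, pmax(-1, cosang))) * .rad2deg
  } else {
    pp <- landmark_xy(series, spec$points[1])
    pq <- landmark_xy(series, spec$points[2])
    d <- pq - pp
    n <- sqrt(rowSums(d^2))
    zero <- which(n == 0)
    if (length(zero))
      stop("coincident points at frame ", zero[1] - 1, " for angle ", spec$name)
    vals <- acos(pmin(1, pmax(-1, d[, 2] / n))) * .rad2deg
  }
  angle_series(spec$name, series$fps, vals)
}

#' Mean of an angle series
#'
#' Arithmetic mean over all frames; the per-repetition summary used for
#' cohort aggregation.
#'
#' @param series An `angle_series`.
#' @return Mean angle in degrees.
#' @export
mean_angle <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  if (!length(series$values)) stop("empty angle series")
  mean(series$values)
}
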