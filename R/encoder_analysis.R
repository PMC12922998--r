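# Quantitative readouts of motion-frame geometry: where the white head and
# each colored tail segment sit, and how color is distributed along a trail.
# These make the encoding's claims measurable — tail color orders by age
# (blue nearest the object, red furthest), the red-to-white vector points
# along the velocity, and acceleration shifts trail energy toward blue.

#' Total chromatic energy of a frame
#'
#' Sum over pixels of `max(channel) - min(channel)`; exactly zero for any
#' achromatic (gray) image, in particular for every post-warm-up motion frame
#' of a static scene.
#'
#' @param frame a `motion_frame`, [color_frame()] or H x W x 3 array.
#' @return non-negative scalar.
#' @export
chromatic_energy <- function(frame) {
  px <- if (is.list(frame)) frame$pixels else frame
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  sum(mx - mn)
}

#' Channel-exclusive energy map
#'
#' The part of one channel exceeding both others,
#' `max(channel - max(other1, other2), 0)`: isolates the tail segment whose
#' age band the channel owns, discarding shared (white/gray) energy such as
#' the current difference.
#'
#' @param frame motion frame or H x W x 3 array.
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @return H x W non-negative matrix.
#' @export
channel_exclusive <- function(frame, channel = c("red", "green", "blue")) {
  channel <- match.arg(channel)
  px <- if (is.list(frame)) frame$pixels else frame
  i <- switch(channel, red = 1L, green = 2L, blue = 3L)
  others <- setdiff(1:3, i)
  pmax(px[, , i] - pmax(px[, , others[1]], px[, , others[2]]), 0)
}

#' White (all-channel) energy map
#'
#' The minimum over channels: energy present in all three, rendering as
#' white/gray — dominated by the current frame difference at the object's
#' present position.
#'
#' @inheritParams channel_exclusive
#' @return H x W non-negative matrix.
#' @export
white_energy <- function(frame) {
  px <- if (is.list(frame)) frame$pixels else frame
  pmin(px[, , 1], px[, , 2], px[, , 3])
}

#' Energy-weighted centroid of a map
#'
#' @param energy H x W non-negative matrix.
#' @return `c(x, y)` in pixel units (pixel centers at half-integers), or
#'   `c(NA, NA)` when the map is all zero.
#' @export
energy_centroid <- function(energy) {
  tot <- sum(energy)
  if (tot <= 0) return(c(NA_real_, NA_real_))
  h <- nrow(energy); w <- ncol(energy)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  c(sum(xs * energy), sum(ys * energy)) / tot
}

#' Centroid of a channel's exclusive energy
#'
#' @inheritParams channel_exclusive
#' @return `c(x, y)` or `c(NA, NA)`.
#' @export
exclusive_centroid <- function(frame, channel) {
  energy_centroid(channel_exclusive(frame, channel))
}

#' Blue-to-red energy ratio on the leading side of a trail
#'
#' Splits the frame by the line through `center` perpendicular to `direction`
#' and compares blue-exclusive to red-exclusive energy on the leading
#' (direction-of-travel) side. Accelerating objects outrun their red tail, so
#' the leading half is blue-shifted; decelerating objects are caught by it,
#' red-shifting the leading half.
#'
#' @param frame motion frame.
#' @param center `c(x, y)` reference point (e.g., the object's true position).
#' @param direction `c(dx, dy)` travel direction (need not be unit length).
#' @param eps floor added to numerator and denominator to stabilize ratios on
#'   near-empty halves.
#' @return scalar ratio `(blue + eps) / (red + eps)`.
#' @export
leading_energy_ratio <- function(frame, center, direction, eps = 1e-6) {
  px <- if (is.list(frame)) frame$pixels else frame
  h <- dim(px)[1]; w <- dim(px)[2]
  u <- direction / sqrt(sum(direction^2))
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  lead <- ((xs - center[1]) * u[1] + (ys - center[2]) * u[2]) > 0
  blue <- sum(channel_exclusive(px, "blue")[lead])
  red <- sum(channel_exclusive(px, "red")[lead])
  (blue + eps) / (red + eps)
}

#' Angle between two 2-D vectors, in degrees
#'
#' @param a,b numeric length-2 vectors.
#' @return angle in `[0, 180]` degrees; `NA` if either vector is zero.
#' @export
angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cosang <- sum(a * b) / (na * nb)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}
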