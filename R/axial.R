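#' Axial (mod-180 degree) angle algebra
#'
#' Nerve fiber orientation is a line direction, not a heading: an angle and
#' the same angle plus 180 degrees describe the same fiber.  All orientation
#' arithmetic in this package therefore runs on the doubled angle, where the
#' wraparound disappears: an axial angle `phi` is represented by the unit
#' vector `(sin 2 phi, cos 2 phi)` and mapped back by halving the resultant's
#' angle.  Angles are stored in radians in `[0, pi)`, measured from the +x
#' image axis toward +y.
#'
#' @param theta Numeric vector of angles in radians.
#' @return `fold_axial()` returns angles reduced to `[0, pi)`.
#' @examples
#' fold_axial(pi + 0.3)           # 0.3
#' axial_distance(0, pi / 2)      # 2, maximal separation
#' axial_mean(c(0.1, 0.1 + pi), c(1, 1))
#' @export
fold_axial <- function(theta) theta %% pi

#' @rdname fold_axial
#' @param s,c Doubled-angle sine and cosine components.
#' @return `axial_from_components()` returns the axial angle in `[0, pi)`
#'   whose doubled-angle vector points along `(s, c)`; `NA` where the
#'   resultant is (near) zero and the mean orientation is undefined.
#' @export
axial_from_components <- function(s, c) {
  ang <- 0.5 * atan2(s, c)
  ang <- ang %% pi
  ang[sqrt(s^2 + c^2) < 1e-12] <- NA_real_
  ang
}

#' Weighted circular mean of axial angles
#'
#' The weighted mean orientation is the half-angle of the weighted resultant
#' of the doubled-angle unit vectors.  It is invariant under replacing any
#' input angle by itself plus 180 degrees.
#'
#' @param angles Numeric vector of axial angles, radians.
#' @param weights Nonnegative weights, same length (default all 1).
#' @return Axial mean in `[0, pi)`.
#' @export
axial_mean <- function(angles, weights = rep(1, length(angles))) {
  stopifnot(length(angles) == length(weights), length(angles) > 0)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (all(weights == 0)) stop("undefined axial mean: all weights are zero")
  s <- sum(weights * sin(2 * angles))
  c <- sum(weights * cos(2 * angles))
  if (sqrt(s^2 + c^2) / sum(weights) < 1e-12) {
    stop("undefined axial mean: doubled-angle resultant is zero")
  }
  (0.5 * atan2(s, c)) %% pi
}

#' Distance between two axial angles
#'
#' Euclidean distance between the doubled-angle unit vectors, equal to
#' `2 * |sin(a - b)|`.  Ranges from 0 (parallel lines) to 2 (perpendicular).
#'
#' @param a,b Axial angles in radians (vectorized, recycled).
#' @return Numeric in `[0, 2]`.
#' @export
axial_distance <- function(a, b) {
  sqrt((sin(2 * a) - sin(2 * b))^2 + (cos(2 * a) - cos(2 * b))^2)
}

## wrap a degree difference into (-180, 180]
wrap180 <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

## circular mean of angles in degrees (full 360 circle); error if degenerate
circ_mean_deg <- function(x) {
  s <- mean(sin(x * pi / 180))
  c <- mean(cos(x * pi / 180))
  if (sqrt(s^2 + c^2) < 1e-8) {
    stop("undefined circular mean: resultant length is zero")
  }
  (atan2(s, c) * 180 / pi) %% 360
}
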