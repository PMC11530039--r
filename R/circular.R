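#' Wrap angles to (-pi, pi]
#'
#' Reduces arbitrary angles to the principal branch used throughout the
#' package. The branch is half-open at \eqn{-\pi}: a value that would wrap to
#' exactly \eqn{-\pi} is reported as \eqn{\pi}.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length, in (-pi, pi].
#' @export
#' @examples
#' wrap_angle(c(0, 3 * pi / 2, -pi))
wrap_angle <- function(theta) {
  w <- ((theta + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

#' Circular mean and resultant length
#'
#' Mean direction of a set of angles via the resultant vector. Arithmetic
#' averaging of angles is wrong near the +/-pi wrap; the resultant-vector
#' angle is not.
#'
#' @param theta numeric vector of angles in radians.
#' @return list with `mean` (radians, in (-pi, pi]) and `resultant_length`
#'   (in \[0, 1\]; near 0 means the directions nearly cancel and the mean is
#'   meaningless).
#' @export
circ_mean <- function(theta) {
  s <- mean(sin(theta))
  c <- mean(cos(theta))
  list(mean = atan2(s, c), resultant_length = sqrt(s^2 + c^2))
}

#' Circular correlation between two angle series
#'
#' Fisher--Lee circular correlation coefficient. It is invariant to a global
#' rotation of either series; reflecting one series negates it.
#'
#' @param alpha,beta numeric vectors of angles in radians, equal length.
#' @return correlation in \[-1, 1\].
#' @export
circ_cor <- function(alpha, beta) {
  stopifnot(length(alpha) == length(beta), length(alpha) >= 2L)
  a0 <- circ_mean(alpha)$mean
  b0 <- circ_mean(beta)$mean
  sa <- sin(alpha - a0)
  sb <- sin(beta - b0)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}

#' Causally unwrap a phase series
#'
#' Accumulates the wrapped sample-to-sample increments so the result is a
#' continuous real-valued phase. Each output sample depends only on inputs up
#' to that sample.
#'
#' @param theta numeric vector of wrapped angles in radians.
#' @return numeric vector; `unwrap_phase(theta)[1] == theta[1]`.
#' @export
unwrap_phase <- function(theta) {
  if (length(theta) <= 1L) return(theta)
  theta[1] + c(0, cumsum(wrap_angle(diff(theta))))
}
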