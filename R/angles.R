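#' Wrap angles to the canonical heading range
#'
#' Headings are expressed in degrees on `(-180, 180]`, with 0 = straight
#' forward and positive angles clockwise (rightward) when viewed from above.
#' All wrapping in the package goes through this one utility.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to `(-180, 180]`.
#' @examples
#' wrap_angle(c(190, -180, 360, 180))
#' @export
wrap_angle <- function(x) {
  180 - ((180 - x) %% 360)
}

#' Circular mean of heading angles
#'
#' Mean direction of a sample of angles, computed from the resultant of the
#' unit vectors. Undefined (degenerate) when the mean resultant length is
#' numerically zero, e.g. for two diametrically opposed angles.
#'
#' @param angles_deg numeric vector of angles in degrees (any representation;
#'   wrapped internally).
#' @return mean direction in degrees on `(-180, 180]`.
#' @seealso [circular_sd_deg()]
#' @examples
#' circular_mean_deg(c(179, -179)) # 180, not 0
#' @export
circular_mean_deg <- function(angles_deg) {
  if (length(angles_deg) == 0L) {
    stop("circular_mean_deg(): empty angle vector", call. = FALSE)
  }
  rad <- angles_deg * pi / 180
  s <- mean(sin(rad))
  c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) <= 1e-9) {
    stop("circular_mean_deg(): resultant length is zero; mean direction undefined",
         call. = FALSE)
  }
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Circular standard deviation of heading angles
#'
#' Wrapped-normal-equivalent dispersion \eqn{\sqrt{-2\ln \bar R}} converted to
#' degrees, where \eqn{\bar R} is the mean resultant length. At small
#' dispersion this coincides with the ordinary standard deviation of the
#' wrapped deviations, which is how per-heading variability is reported.
#'
#' @inheritParams circular_mean_deg
#' @return circular standard deviation in degrees (0 for identical angles).
#' @export
circular_sd_deg <- function(angles_deg) {
  if (length(angles_deg) == 0L) {
    stop("circular_sd_deg(): empty angle vector", call. = FALSE)
  }
  rad <- angles_deg * pi / 180
  rbar <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  rbar <- min(rbar, 1) # guard fp overshoot
  if (1 - rbar < 1e-10) {
    # sqrt(-2 log Rbar) loses precision as Rbar -> 1; at such small
    # dispersion it coincides with the RMS wrapped deviation from the mean
    m <- wrap_angle(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
    return(sqrt(mean(wrap_angle(angles_deg - m)^2)))
  }
  sqrt(-2 * log(rbar)) * 180 / pi
}

# Unit vector (head-fixed frame: x forward, y leftward, z up) for a heading
# angle measured clockwise-positive from above, i.e. +90 deg points rightward
# along -y.
heading_unit_vector <- function(heading_deg) {
  rad <- heading_deg * pi / 180
  c(cos(rad), -sin(rad), 0)
}

# Inverse of heading_unit_vector restricted to the horizontal plane.
heading_from_xy <- function(x, y) {
  wrap_angle(unname(atan2(-y, x)) * 180 / pi)
}

# Evaluate code with a temporary, restored RNG state. All simulation entry
# points take an explicit seed and leave the caller's RNG untouched.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}
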