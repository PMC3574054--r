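#' Gaussian-speed translation profile
#'
#' Constructs the kinematics of a passive linear translation with a Gaussian
#' speed profile: \eqn{v(t) = A \exp(-(t - T/2)^2 / (2\sigma^2))} on
#' `[0, T]`, truncated to zero outside, with \eqn{\sigma = T/6} (so the
#' profile spans +/- 3 SD) and amplitude \eqn{A} scaled so that the integral
#' of speed equals the requested displacement. The default laboratory
#' stimulus is a 1 s, 13 cm translation, giving a peak velocity of about
#' 0.31 m/s and peak acceleration/deceleration of about 1.13 m/s^2.
#'
#' Peak velocity is the profile maximum \eqn{A}; peak acceleration is the
#' maximum of \eqn{|dv/dt|}, attained at the inflection points
#' \eqn{t = T/2 \pm \sigma}.
#'
#' @param duration_s translation duration in seconds (> 0).
#' @param displacement_m total displacement in meters (>= 0).
#' @return an object of class `motion_profile`: a list with fields
#'   `duration_s`, `displacement_m`, `sigma_s`, `peak_velocity_m_s`,
#'   `peak_accel_m_s2`.
#' @examples
#' p <- make_motion_profile(1, 0.13)
#' p$peak_velocity_m_s # ~0.31
#' p$peak_accel_m_s2   # ~1.13
#' @export
make_motion_profile <- function(duration_s, displacement_m) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("make_motion_profile(): duration_s must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(displacement_m) || length(displacement_m) != 1L || displacement_m < 0) {
    stop("make_motion_profile(): displacement_m must be a non-negative scalar", call. = FALSE)
  }
  sigma <- duration_s / 6
  # mass of a +/-3 SD truncated Gaussian: sigma * sqrt(2*pi) * (2*pnorm(3) - 1)
  area <- sigma * sqrt(2 * pi) * (2 * stats::pnorm(3) - 1)
  amp <- displacement_m / area
  structure(
    list(
      duration_s = duration_s,
      displacement_m = displacement_m,
      sigma_s = sigma,
      peak_velocity_m_s = amp,
      peak_accel_m_s2 = amp * exp(-0.5) / sigma
    ),
    class = "motion_profile"
  )
}

#' Speed and acceleration of a motion profile
#'
#' Evaluate the Gaussian speed profile and its time derivative. Outside
#' `[0, duration_s]` both are zero.
#'
#' @param profile a [make_motion_profile()] object.
#' @param t_s numeric vector of times in seconds.
#' @return numeric vector, m/s for `profile_speed`, m/s^2 for
#'   `profile_accel` (signed: positive while speeding up).
#' @export
profile_speed <- function(profile, t_s) {
  stopifnot(inherits(profile, "motion_profile"))
  mid <- profile$duration_s / 2
  v <- profile$peak_velocity_m_s *
    exp(-(t_s - mid)^2 / (2 * profile$sigma_s^2))
  v[t_s < 0 | t_s > profile$duration_s] <- 0
  v
}

#' @rdname profile_speed
#' @export
profile_accel <- function(profile, t_s) {
  stopifnot(inherits(profile, "motion_profile"))
  mid <- profile$duration_s / 2
  a <- -(t_s - mid) / profile$sigma_s^2 * profile_speed(profile, t_s)
  a[t_s < 0 | t_s > profile$duration_s] <- 0
  a
}

#' @export
print.motion_profile <- function(x, ...) {
  cat(sprintf(
    "Gaussian-speed motion profile: %.3g s, %.3g m (peak vel %.3g m/s, peak accel %.3g m/s^2)\n",
    x$duration_s, x$displacement_m, x$peak_velocity_m_s, x$peak_accel_m_s2
  ))
  invisible(x)
}
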