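# Standard gravity used to express accelerations in g units. Decoded
# headings are invariant to this constant (gravity cancels in the
# peak-to-trough response), so it only fixes firing-rate units.
G_M_S2 <- 9.80665

#' Otolith-afferent firing rate
#'
#' Linear gravito-inertial firing model `d = s * (F . P) + d0`, where `F`
#' is the total force in g (gravity plus inertial acceleration), `P` the
#' unit polarization vector, `s` the sensitivity and `d0` the resting
#' discharge. Rates may be negative unless `rectify = TRUE`.
#'
#' @param pop a `neural_population` (one or more neurons).
#' @param force_g length-3 force vector in g units (head-fixed frame).
#' @param rectify clip negative rates to zero.
#' @return numeric vector of firing rates, spikes/s.
#' @examples
#' n <- neurons(0, 0, sensitivity = 35, resting_discharge = 90)
#' afferent_rate(n, c(1, 0, 0)) # 125
#' @export
afferent_rate <- function(pop, force_g, rectify = FALSE) {
  stopifnot(inherits(pop, "neural_population"), length(force_g) == 3)
  d <- pop$sensitivity * drop(polarization_matrix(pop) %*% force_g) +
    pop$resting_discharge
  if (rectify) d <- pmax(d, 0)
  d
}

#' Peak-to-trough response to a translation
#'
#' The information conveyed by each neuron about a transient translation is
#' quantified as the firing rate at the point of maximum acceleration minus
#' the rate at the point of maximum deceleration. For the linear afferent
#' model this equals `2 * s * a_peak * (u(theta) . P)` with `a_peak` in g:
#' gravity and the resting discharge cancel exactly. The closed form is the
#' default; `method = "time_resolved"` evaluates the full model at the
#' numerically located acceleration extrema of the sampled profile and
#' agrees with the closed form to numerical precision.
#'
#' @param pop a `neural_population`.
#' @param profile a [make_motion_profile()].
#' @param heading_deg stimulus heading (deg, horizontal plane).
#' @param method `"closed_form"` or `"time_resolved"`.
#' @param gravity_g gravity vector in g units (default upright head,
#'   `c(0, 0, -1)`); inert for horizontal stimuli.
#' @param rectify clip negative instantaneous rates (time-resolved path and
#'   closed form alike) before differencing.
#' @return numeric vector of peak-to-trough modulations, spikes/s.
#' @export
peak_to_trough_response <- function(pop, profile, heading_deg,
                                    method = c("closed_form", "time_resolved"),
                                    gravity_g = c(0, 0, -1), rectify = FALSE) {
  stopifnot(inherits(pop, "neural_population"),
            inherits(profile, "motion_profile"))
  method <- match.arg(method)
  u <- heading_unit_vector(heading_deg)
  a_peak_g <- profile$peak_accel_m_s2 / G_M_S2
  if (method == "closed_form" && !rectify) {
    return(2 * pop$sensitivity * a_peak_g *
             drop(polarization_matrix(pop) %*% u))
  }
  if (method == "closed_form") {
    f_acc <- gravity_g + a_peak_g * u
    f_dec <- gravity_g - a_peak_g * u
  } else {
    mid <- profile$duration_s / 2
    t_acc <- stats::optimize(function(t) profile_accel(profile, t),
                             c(0, mid), maximum = TRUE, tol = 1e-12)$maximum
    t_dec <- stats::optimize(function(t) profile_accel(profile, t),
                             c(mid, profile$duration_s), tol = 1e-12)$minimum
    f_acc <- gravity_g + profile_accel(profile, t_acc) / G_M_S2 * u
    f_dec <- gravity_g + profile_accel(profile, t_dec) / G_M_S2 * u
  }
  afferent_rate(pop, f_acc, rectify = rectify) -
    afferent_rate(pop, f_dec, rectify = rectify)
}

#' Mirror a left-labyrinth population across the mid-sagittal plane
#'
#' Appends to each neuron its mirror image (azimuth negated; elevation,
#' sensitivity and resting discharge preserved), simulating an overall
#' bilateral population from unilaterally reported polarization vectors.
#'
#' @param pop a left-only `neural_population`.
#' @return a bilateral `neural_population` with `2n` neurons (originals
#'   first, mirrors second, in order).
#' @export
mirror_bilateral <- function(pop) {
  stopifnot(inherits(pop, "neural_population"))
  if (population_laterality(pop) != "left-only") {
    stop("mirror_bilateral(): population is already bilateral", call. = FALSE)
  }
  mirrored <- as.data.frame(pop)
  mirrored$azimuth_deg <- wrap_angle(-mirrored$azimuth_deg)
  new_population(rbind(as.data.frame(pop), mirrored), "bilateral")
}

#' Population-vector heading decode
#'
#' Decodes a heading stimulus from a bilateral population: each neuron's
#' scalar peak-to-trough response multiplies its polarization vector, the
#' vectors are summed, and the decoded heading is the angle of the
#' horizontal projection of the sum. Non-uniform preferred-direction
#' distributions bias the decode toward overrepresented directions.
#'
#' @inheritParams peak_to_trough_response
#' @param ... passed to [peak_to_trough_response()] (e.g. `rectify`,
#'   `method`).
#' @return decoded heading in degrees on `(-180, 180]`.
#' @export
decode_heading <- function(pop, profile, heading_deg, ...) {
  if (population_laterality(pop) != "bilateral") {
    stop("decode_heading(): population must be bilateral", call. = FALSE)
  }
  r <- peak_to_trough_response(pop, profile, heading_deg, ...)
  v <- drop(crossprod(polarization_matrix(pop), r))
  if (sqrt(v[1]^2 + v[2]^2) <= 1e-9) {
    stop("decode_heading(): degenerate population vector (zero horizontal projection)",
         call. = FALSE)
  }
  heading_from_xy(v[1], v[2])
}

#' Decoded bias curve over a set of headings
#'
#' Applies [decode_heading()] to each stimulus and returns the wrapped bias
#' (decoded minus stimulus) per heading; evaluated at the 48 identification
#' headings this is the population-vector bias prediction comparable to the
#' behavioral curves.
#'
#' @inheritParams decode_heading
#' @param headings_deg stimulus headings (deg).
#' @return a `bias_curve` data.frame with columns `stimulus_deg`,
#'   `decoded_deg`, `bias_deg`.
#' @export
decode_bias_curve <- function(pop, profile,
                              headings_deg = wrap_angle(seq(0, 352.5, by = 7.5)),
                              ...) {
  decoded <- vapply(headings_deg, function(th) {
    decode_heading(pop, profile, th, ...)
  }, numeric(1))
  df <- data.frame(
    stimulus_deg = wrap_angle(headings_deg),
    decoded_deg = decoded,
    bias_deg = wrap_angle(decoded - headings_deg)
  )
  df <- df[order(df$stimulus_deg), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("decoded_bias_curve", "data.frame"))
}
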