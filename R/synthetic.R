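#' Simulated heading-identification observer
#'
#' An observer for the identification task: the indicated heading is the
#' stimulus plus a deterministic signed bias plus wrapped-normal response
#' noise, with an optional lapse process that replaces the response by a
#' uniform random direction.
#'
#' The default bias function is the smooth lateral-attraction shape
#' \eqn{b(\theta) = A \sin(2\theta)} with amplitude `bias_amp_deg`:
#' overestimation of forward headings, underestimation of backward ones, and
#' zero bias at 0, +/-90 and 180 degrees. The default amplitude of 6 degrees
#' matches the magnitude of the largest behaviorally observed biases.
#'
#' @param bias_fn function mapping heading (deg) to signed bias (deg);
#'   vectorized. Defaults to `bias_amp_deg * sin(2*theta)`.
#' @param noise_sd_fn function mapping heading (deg) to response SD (deg);
#'   must be positive. Defaults to a constant `noise_sd_deg`.
#' @param lapse_rate probability in `[0, 1)` of a uniform-random response.
#' @param bias_amp_deg amplitude of the default bias function (deg).
#' @param noise_sd_deg value of the default constant noise SD (deg).
#' @return object of class `id_observer`.
#' @examples
#' obs <- id_observer(noise_sd_deg = 5)
#' obs$bias_fn(45) # 6
#' @export
id_observer <- function(bias_fn = NULL, noise_sd_fn = NULL, lapse_rate = 0,
                        bias_amp_deg = 6, noise_sd_deg = 5) {
  if (is.null(bias_fn)) {
    force(bias_amp_deg)
    bias_fn <- function(theta_deg) bias_amp_deg * sin(2 * theta_deg * pi / 180)
  }
  if (is.null(noise_sd_fn)) {
    force(noise_sd_deg)
    noise_sd_fn <- function(theta_deg) rep(noise_sd_deg, length(theta_deg))
  }
  stopifnot(is.function(bias_fn), is.function(noise_sd_fn))
  if (!is.numeric(lapse_rate) || lapse_rate < 0 || lapse_rate >= 1) {
    stop("id_observer(): lapse_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(noise_sd_fn(seq(-180, 180, by = 15)) <= 0)) {
    stop("id_observer(): noise_sd_fn must be positive everywhere", call. = FALSE)
  }
  structure(list(bias_fn = bias_fn, noise_sd_fn = noise_sd_fn,
                 lapse_rate = lapse_rate),
            class = "id_observer")
}

#' Identification experiment design
#'
#' The standard design presents 48 heading directions (0 to 352.5 deg in
#' 7.5 deg steps) twice per block over 5 blocks, i.e. 10 presentations per
#' heading and 480 trials per subject. Stimulus angles are stored in the
#' canonical `(-180, 180]` convention.
#'
#' @param headings_deg stimulus angles in degrees.
#' @param n_blocks number of blocks.
#' @param reps_per_block repetitions of each heading within a block.
#' @return object of class `id_design`.
#' @export
identification_design <- function(headings_deg = seq(0, 352.5, by = 7.5),
                                  n_blocks = 5, reps_per_block = 2) {
  stopifnot(length(headings_deg) >= 1, n_blocks >= 1, reps_per_block >= 1)
  headings <- wrap_angle(headings_deg)
  if (anyDuplicated(headings)) {
    stop("identification_design(): duplicate heading angles", call. = FALSE)
  }
  structure(list(headings_deg = headings,
                 n_blocks = as.integer(n_blocks),
                 reps_per_block = as.integer(reps_per_block)),
            class = "id_design")
}

#' Number of measurements in an identification design
#'
#' @param design an [identification_design()].
#' @param n_subjects number of subjects.
#' @return total trial count `n_subjects * n_blocks * reps_per_block *
#'   n_headings` (5760 for twelve subjects under the default design).
#' @export
n_measurements <- function(design, n_subjects = 1) {
  stopifnot(inherits(design, "id_design"))
  n_subjects * design$n_blocks * design$reps_per_block *
    length(design$headings_deg)
}

#' Simulate an identification experiment
#'
#' Generates one trial log row per presentation. The response is
#' `wrap(stimulus + bias_fn(stimulus) + noise)` with wrapped-normal noise of
#' SD `noise_sd_fn(stimulus)`, replaced by a uniform draw on `(-180, 180]`
#' with probability `lapse_rate`. Presentation order is randomized within
#' each block. Identical `(observer, design, seed)` give byte-identical logs.
#'
#' @param observer an [id_observer()].
#' @param design an [identification_design()].
#' @param seed integer seed; the caller's RNG state is untouched.
#' @param subject subject label stored in the log.
#' @return data.frame with columns `subject`, `block`, `presentation`,
#'   `stimulus_deg`, `response_deg`.
#' @export
simulate_identification <- function(observer, design, seed, subject = "s01") {
  stopifnot(inherits(observer, "id_observer"), inherits(design, "id_design"))
  with_local_seed(seed, {
    rows <- lapply(seq_len(design$n_blocks), function(b) {
      stim <- rep(design$headings_deg, design$reps_per_block)
      stim <- stim[sample.int(length(stim))]
      noise <- stats::rnorm(length(stim), 0, observer$noise_sd_fn(stim))
      resp <- wrap_angle(stim + observer$bias_fn(stim) + noise)
      lapse <- stats::runif(length(stim)) < observer$lapse_rate
      if (any(lapse)) {
        resp[lapse] <- wrap_angle(stats::runif(sum(lapse), -180, 180))
      }
      data.frame(subject = subject, block = b,
                 presentation = seq_along(stim),
                 stimulus_deg = stim, response_deg = resp)
    })
    do.call(rbind, rows)
  })
}

#' Simulated 2AFC heading-discrimination observer
#'
#' Responds "clockwise" to a stimulus with probability
#' \eqn{\Phi((\mathrm{wrap}(s - \mathrm{PSE})) / \mathrm{JND})}: a
#' cumulative-Gaussian response rule whose mean and SD are the observer's
#' true point of subjective equality and just-noticeable difference.
#'
#' @param pse_true_deg true PSE in degrees.
#' @param jnd_true_deg true JND in degrees (> 0).
#' @return object of class `afc_observer`.
#' @export
afc_observer <- function(pse_true_deg, jnd_true_deg) {
  stopifnot(is.numeric(pse_true_deg), is.numeric(jnd_true_deg))
  if (jnd_true_deg <= 0) {
    stop("afc_observer(): jnd_true_deg must be positive", call. = FALSE)
  }
  structure(list(pse_true_deg = pse_true_deg, jnd_true_deg = jnd_true_deg),
            class = "afc_observer")
}

#' Probability that the observer reports "clockwise"
#'
#' @param observer an [afc_observer()].
#' @param stimulus_deg stimulus heading(s) in degrees; the comparison with
#'   the observer's PSE is taken on the wrapped difference.
#' @return vector of probabilities.
#' @export
prob_clockwise <- function(observer, stimulus_deg) {
  stopifnot(inherits(observer, "afc_observer"))
  stats::pnorm(wrap_angle(stimulus_deg - observer$pse_true_deg) /
                 observer$jnd_true_deg)
}

#' Draw a 2AFC response
#'
#' Bernoulli draw from [prob_clockwise()] using the current RNG stream
#' (staircase runners wrap this in a seeded context).
#'
#' @inheritParams prob_clockwise
#' @return integer vector of 0/1 responses (1 = clockwise).
#' @export
respond_2afc <- function(observer, stimulus_deg) {
  p <- prob_clockwise(observer, stimulus_deg)
  as.integer(stats::runif(length(p)) < p)
}

# ---- neural populations -----------------------------------------------------

new_population <- function(df, laterality) {
  stopifnot(laterality %in% c("left-only", "bilateral"))
  df <- as.data.frame(df)
  structure(df, laterality = laterality,
            class = c("neural_population", "data.frame"))
}

#' Laterality of a neural population
#' @param pop a `neural_population`.
#' @return `"left-only"` or `"bilateral"`.
#' @export
population_laterality <- function(pop) {
  stopifnot(inherits(pop, "neural_population"))
  attr(pop, "laterality")
}

#' Construct neurons from spherical preferred directions
#'
#' A neuron is defined by its unit polarization vector `P` (the 3-D
#' direction of maximal sensitivity, head-fixed frame: x forward, y
#' leftward, z up), a sensitivity `s` in spikes/s per g, and a resting
#' discharge `d0` in spikes/s; its mean firing rate in response to a
#' gravito-inertial force `F` (in g) is `d = s * (F . P) + d0`.
#' Azimuth follows the heading convention (clockwise-positive from above);
#' elevation is positive upward.
#'
#' @param azimuth_deg,elevation_deg preferred direction in degrees.
#' @param sensitivity spikes/s per g (> 0).
#' @param resting_discharge spikes/s (>= 0).
#' @param laterality population label.
#' @return a `neural_population` data.frame with columns `azimuth_deg`,
#'   `elevation_deg`, `sensitivity`, `resting_discharge`.
#' @export
neurons <- function(azimuth_deg, elevation_deg = 0, sensitivity = 1,
                    resting_discharge = 0, laterality = "left-only") {
  n <- length(azimuth_deg)
  df <- data.frame(
    azimuth_deg = wrap_angle(azimuth_deg),
    elevation_deg = rep_len(elevation_deg, n),
    sensitivity = rep_len(sensitivity, n),
    resting_discharge = rep_len(resting_discharge, n)
  )
  if (any(df$sensitivity <= 0)) {
    stop("neurons(): sensitivity must be positive", call. = FALSE)
  }
  if (any(df$resting_discharge < 0)) {
    stop("neurons(): resting_discharge must be non-negative", call. = FALSE)
  }
  if (any(abs(df$elevation_deg) > 90)) {
    stop("neurons(): elevation must lie in [-90, 90]", call. = FALSE)
  }
  new_population(df, laterality)
}

#' Unit polarization vectors of a population
#'
#' @param pop a `neural_population`.
#' @return n x 3 matrix of unit vectors (columns x, y, z).
#' @export
polarization_matrix <- function(pop) {
  az <- pop$azimuth_deg * pi / 180
  el <- pop$elevation_deg * pi / 180
  cbind(x = cos(el) * cos(az),
        y = -cos(el) * sin(az),
        z = sin(el))
}

#' Synthetic otolith-afferent population
#'
#' Draws a left-labyrinth population whose horizontal-projection azimuths
#' follow a unimodal wrapped-normal distribution centered at
#' `azimuth_peak_deg` (default +50 deg; the bilateral mirror supplies the
#' -50 deg peak, reproducing the lateral peaks and fore/aft troughs of
#' otolith-afferent preferred directions). Elevations are uniform on
#' `+/- elevation_spread_deg`; sensitivities are log-normal around
#' `sensitivity_mean` spikes/s/g; resting discharges are normal around
#' `resting_mean` spikes/s (truncated at zero). Decoded headings are
#' invariant to the sensitivity scale and resting discharge, so these
#' magnitudes only set plausible firing-rate units.
#'
#' @param n number of neurons (>= 1).
#' @param azimuth_peak_deg center of the azimuth distribution (deg).
#' @param azimuth_spread_deg wrapped-normal SD of azimuths (deg).
#' @param seed integer seed.
#' @param elevation_spread_deg half-range of uniform elevations (deg).
#' @param sensitivity_mean median sensitivity, spikes/s per g.
#' @param resting_mean mean resting discharge, spikes/s.
#' @return a left-only `neural_population` of `n` neurons.
#' @export
make_afferent_population <- function(n, azimuth_peak_deg = 50,
                                     azimuth_spread_deg = 30, seed = 1,
                                     elevation_spread_deg = 60,
                                     sensitivity_mean = 35,
                                     resting_mean = 90) {
  stopifnot(n >= 1)
  with_local_seed(seed, {
    az <- wrap_angle(stats::rnorm(n, azimuth_peak_deg, azimuth_spread_deg))
    el <- stats::runif(n, -elevation_spread_deg, elevation_spread_deg)
    s <- stats::rlnorm(n, log(sensitivity_mean), 0.3)
    d0 <- pmax(stats::rnorm(n, resting_mean, 10), 0)
    neurons(az, el, s, d0, laterality = "left-only")
  })
}

#' Synthetic cosine-tuned (MSTd-like) population
#'
#' Builds a bilateral population of horizontal-plane cosine-tuned units
#' whose preferred directions are drawn from a two-component wrapped-normal
#' mixture with peaks at `azimuth_peaks_deg` (default +/-90 deg, the
#' lateral overrepresentation reported for MSTd heading tuning). Exact
#' mirror symmetry is enforced by drawing `n/2` units from the first
#' component and mirroring them, so the peaks must be a mirror pair. An
#' infinite spread gives the uniform special case.
#'
#' @param n total number of units (even, >= 2).
#' @param azimuth_peaks_deg length-2 mirror pair of azimuth peaks (deg).
#' @param azimuth_spread_deg SD of each mixture component (deg); `Inf` for
#'   a uniform distribution.
#' @param seed integer seed.
#' @return a bilateral `neural_population` of `n` unit-sensitivity,
#'   zero-resting-discharge horizontal neurons.
#' @export
make_cosine_population <- function(n, azimuth_peaks_deg = c(90, -90),
                                   azimuth_spread_deg = 25, seed = 1) {
  stopifnot(n >= 2)
  if (n %% 2 != 0) {
    stop("make_cosine_population(): n must be even (bilateral population)",
         call. = FALSE)
  }
  if (length(azimuth_peaks_deg) != 2 ||
      abs(wrap_angle(azimuth_peaks_deg[1] + azimuth_peaks_deg[2])) > 1e-9) {
    stop("make_cosine_population(): azimuth peaks must be a mirror pair (a, -a)",
         call. = FALSE)
  }
  half <- with_local_seed(seed, {
    az <- if (is.infinite(azimuth_spread_deg)) {
      stats::runif(n / 2, -180, 180)
    } else {
      stats::rnorm(n / 2, azimuth_peaks_deg[1], azimuth_spread_deg)
    }
    neurons(wrap_angle(az), elevation_deg = 0, sensitivity = 1,
            resting_discharge = 0, laterality = "left-only")
  })
  mirror_bilateral(half)
}
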