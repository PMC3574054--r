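#' Heading-dependent likelihood profile
#'
#' Piecewise-linear table of the sensory likelihood SD as a function of
#' absolute heading eccentricity (symmetric about straight ahead). The
#' shipped default tables are illustrative: SDs increase with eccentricity,
#' with forward-heading magnitudes anchored to the ~4 deg vestibular and
#' ~1 deg visual forward discrimination thresholds typical of the
#' literature. They are configuration, not ground truth, and can be edited
#' or loaded from YAML ([read_likelihood_profile()]).
#'
#' @param nodes data.frame with columns `heading_deg` (in `[0, 180]`) and
#'   `sd_deg` (> 0).
#' @return object of class `likelihood_profile`.
#' @export
likelihood_profile <- function(nodes) {
  stopifnot(is.data.frame(nodes),
            all(c("heading_deg", "sd_deg") %in% names(nodes)))
  if (any(nodes$heading_deg < 0 | nodes$heading_deg > 180)) {
    stop("likelihood_profile(): nodes must lie in [0, 180] degrees", call. = FALSE)
  }
  if (any(nodes$sd_deg <= 0)) {
    stop("likelihood_profile(): sd_deg must be positive", call. = FALSE)
  }
  nodes <- nodes[order(nodes$heading_deg), , drop = FALSE]
  if (anyDuplicated(nodes$heading_deg)) {
    stop("likelihood_profile(): duplicate node headings", call. = FALSE)
  }
  structure(list(nodes = nodes), class = "likelihood_profile")
}

#' @rdname likelihood_profile
#' @param modality which illustrative default table to return.
#' @export
default_likelihood_profile <- function(modality = c("vestibular", "visual")) {
  modality <- match.arg(modality)
  nodes <- switch(modality,
    vestibular = data.frame(heading_deg = c(0, 45, 90, 135, 180),
                            sd_deg = c(4, 11, 18, 25, 30)),
    visual = data.frame(heading_deg = c(0, 45, 90, 135, 180),
                        sd_deg = c(1.5, 6, 12, 18, 24))
  )
  likelihood_profile(nodes)
}

#' Likelihood SD at a heading
#'
#' Piecewise-linear interpolation of the profile in `|heading|`; constant
#' extrapolation beyond the outermost nodes.
#'
#' @param profile a [likelihood_profile()].
#' @param heading_deg heading angle(s), deg.
#' @return SD in degrees.
#' @export
likelihood_sd <- function(profile, heading_deg) {
  stopifnot(inherits(profile, "likelihood_profile"))
  ecc <- abs(wrap_angle(heading_deg))
  stats::approx(profile$nodes$heading_deg, profile$nodes$sd_deg,
                xout = ecc, rule = 2)$y
}

#' Bimodal lateral prior
#'
#' Prior over heading composed of two equally weighted wrapped Gaussians
#' centered at +/-90 deg with common SD `sigma_prior_deg` - the single
#' free parameter of the Bayesian observer.
#'
#' @param sigma_prior_deg SD of each component, deg (> 0).
#' @param peak_deg magnitude of the peak locations (fixed at 90 for the
#'   lateral prior).
#' @return object of class `bimodal_prior`.
#' @export
bimodal_prior <- function(sigma_prior_deg, peak_deg = 90) {
  if (sigma_prior_deg <= 0) {
    stop("bimodal_prior(): sigma_prior_deg must be positive", call. = FALSE)
  }
  structure(list(sigma_prior_deg = sigma_prior_deg, peak_deg = peak_deg),
            class = "bimodal_prior")
}

# Wrapped-normal density on the circle (degrees); enough replicates of the
# line density to cover +/-3 SD. Very large SDs are numerically uniform.
wrapped_normal_density <- function(x_deg, mean_deg, sd_deg) {
  if (sd_deg >= 5e3) {
    return(rep(1 / 360, length(x_deg)))
  }
  k_max <- min(ceiling(3 * sd_deg / 360) + 1, 60)
  d <- 0
  for (k in -k_max:k_max) {
    d <- d + stats::dnorm(x_deg - mean_deg + 360 * k, 0, sd_deg)
  }
  d
}

prior_density <- function(prior, x_deg) {
  0.5 * wrapped_normal_density(x_deg, prior$peak_deg, prior$sigma_prior_deg) +
    0.5 * wrapped_normal_density(x_deg, -prior$peak_deg, prior$sigma_prior_deg)
}

#' Maximum-a-posteriori heading estimate
#'
#' Multiplies a wrapped-Gaussian likelihood centered at the stimulus (SD
#' given by the likelihood profile evaluated at the stimulus) with the
#' bimodal lateral prior on a dense wrapped grid and returns the grid
#' argmax. Numerical ties are broken toward the stimulus angle; an exactly
#' symmetric pair of maxima (as arises at 0 and 180 deg) resolves to the
#' stimulus itself, i.e. zero bias. Negative stimuli are evaluated by the
#' model's exact mirror symmetry, making predicted bias curves
#' antisymmetric by construction.
#'
#' @param stimulus_deg stimulus heading, deg.
#' @param prior a [bimodal_prior()].
#' @param lik a [likelihood_profile()].
#' @param grid_step_deg posterior grid resolution, deg (<= 0.5).
#' @return MAP heading estimate in degrees.
#' @export
map_estimate <- function(stimulus_deg, prior, lik, grid_step_deg = 0.1) {
  stopifnot(inherits(prior, "bimodal_prior"), inherits(lik, "likelihood_profile"))
  if (grid_step_deg > 0.5) {
    stop("map_estimate(): grid_step_deg must be <= 0.5", call. = FALSE)
  }
  grid <- seq(-180 + grid_step_deg, 180, by = grid_step_deg)
  map_estimate_on_grid(wrap_angle(stimulus_deg), lik, grid,
                       prior_density(prior, grid), grid_step_deg)
}

# Core MAP step for one stimulus given a precomputed prior on the grid.
# Negative stimuli are evaluated through the model's exact mirror symmetry.
map_estimate_on_grid <- function(s, lik, grid, prior_d, grid_step_deg) {
  if (s < 0) {
    return(wrap_angle(-Recall(-s, lik, grid, prior_d, grid_step_deg)))
  }
  post <- wrapped_normal_density(grid, s, likelihood_sd(lik, s)) * prior_d
  cand <- grid[post >= max(post) * (1 - 1e-12)]
  d <- abs(wrap_angle(cand - s))
  near <- cand[d <= min(d) + grid_step_deg / 2]
  offs <- wrap_angle(near - s)
  if (any(offs > grid_step_deg / 2) && any(offs < -grid_step_deg / 2)) {
    return(s) # symmetric tie: zero bias
  }
  near[which.min(abs(offs))]
}

#' Model-predicted bias curve
#'
#' Wrapped bias of the MAP estimate at each heading. Antisymmetric in
#' heading and exactly zero at 0 and 180 deg by the symmetric tie-break.
#'
#' @inheritParams map_estimate
#' @param headings_deg stimulus headings, deg.
#' @return a `bias_curve` data.frame.
#' @export
predict_bias_curve <- function(prior, lik,
                               headings_deg = wrap_angle(seq(0, 352.5, by = 7.5)),
                               grid_step_deg = 0.1) {
  stopifnot(inherits(prior, "bimodal_prior"), inherits(lik, "likelihood_profile"))
  h <- wrap_angle(headings_deg)
  grid <- seq(-180 + grid_step_deg, 180, by = grid_step_deg)
  prior_d <- prior_density(prior, grid)
  # the model is mirror-symmetric: evaluate each |heading| once
  ecc <- unique(abs(h))
  est_pos <- vapply(ecc, map_estimate_on_grid, numeric(1),
                    lik = lik, grid = grid, prior_d = prior_d,
                    grid_step_deg = grid_step_deg)
  est <- sign(h) * est_pos[match(abs(h), ecc)]
  bias_curve(h, wrap_angle(est - h))
}

#' Predicted-bias table over a grid of prior widths
#'
#' Precomputes model-predicted biases for every sigma in a scan grid.
#' Predictions do not depend on observed data, so this table can be shared
#' across repeated [fit_sigma_prior()] calls (e.g. Monte-Carlo parameter
#' recovery) at large savings.
#'
#' @param lik a [likelihood_profile()].
#' @param headings_deg headings at which biases are predicted.
#' @param sigmas_deg scan grid of prior SDs, deg.
#' @param grid_step_deg posterior grid resolution.
#' @return object of class `sigma_scan`: list with `sigmas_deg`,
#'   `headings_deg`, and matrix `bias_deg` (rows = sigmas).
#' @export
sigma_prior_scan <- function(lik, headings_deg,
                             sigmas_deg = seq(5, 120, by = 0.5),
                             grid_step_deg = 0.1) {
  headings <- sort(wrap_angle(headings_deg))
  bias <- t(vapply(sigmas_deg, function(sg) {
    predict_bias_curve(bimodal_prior(sg), lik, headings,
                       grid_step_deg)$bias_deg
  }, numeric(length(headings))))
  structure(list(sigmas_deg = sigmas_deg,
                 headings_deg = headings,
                 bias_deg = bias),
            class = "sigma_scan")
}

#' Least-squares fit of the prior width
#'
#' Finds the prior SD minimizing the sum of squared differences between an
#' observed bias curve and the model-predicted one: a dense scan over
#' `search_range` (0.5 deg resolution by default), optionally followed by a
#' golden-section refinement inside the bracketing interval. Reports
#' `R^2 = 1 - SS_res / SS_tot` about the mean observed bias (negative when
#' the model does worse than the mean; `r_squared_zero` additionally
#' reports the about-zero variant). A solution at the edge of the search
#' range sets `boundary = TRUE`.
#'
#' @param observed a `bias_curve` with at least 8 headings (typically with
#'   0 and 180 deg excluded, where bias vanishes by symmetry).
#' @param lik a [likelihood_profile()].
#' @param search_range length-2 interval of candidate sigmas, deg.
#' @param step_deg scan resolution, deg.
#' @param refine golden-section refinement of the scan minimum.
#' @param scan optional precomputed [sigma_prior_scan()] (its headings must
#'   match the observed curve); implies `refine = FALSE`.
#' @param grid_step_deg posterior grid resolution.
#' @return object of class `sigma_fit`: list with `sigma_prior_hat_deg`,
#'   `r_squared`, `r_squared_zero`, `residuals_deg`, `boundary`.
#' @export
fit_sigma_prior <- function(observed, lik, search_range = c(5, 120),
                            step_deg = 0.5, refine = TRUE, scan = NULL,
                            grid_step_deg = 0.1) {
  stopifnot(inherits(observed, "data.frame"))
  obs <- observed[is.finite(observed$bias_deg), , drop = FALSE]
  obs <- obs[order(wrap_angle(obs$stimulus_deg)), , drop = FALSE]
  obs$stimulus_deg <- wrap_angle(obs$stimulus_deg)
  if (nrow(obs) < 8) {
    stop("fit_sigma_prior(): need at least 8 observed headings", call. = FALSE)
  }
  if (is.null(scan)) {
    sigmas <- seq(search_range[1], search_range[2], by = step_deg)
    scan <- sigma_prior_scan(lik, obs$stimulus_deg, sigmas, grid_step_deg)
  } else {
    stopifnot(inherits(scan, "sigma_scan"))
    if (length(scan$headings_deg) != nrow(obs) ||
        any(abs(scan$headings_deg - obs$stimulus_deg) > 1e-9)) {
      stop("fit_sigma_prior(): scan headings do not match observed curve",
           call. = FALSE)
    }
    sigmas <- scan$sigmas_deg
    refine <- FALSE
  }
  ss <- colSums((t(scan$bias_deg) - obs$bias_deg)^2)
  i <- which.min(ss)
  sigma_hat <- sigmas[i]
  boundary <- i == 1L || i == length(sigmas)
  if (refine && !boundary) {
    obj <- function(sg) {
      pred <- predict_bias_curve(bimodal_prior(sg), lik, obs$stimulus_deg,
                                 grid_step_deg)$bias_deg
      sum((obs$bias_deg - pred)^2)
    }
    opt <- stats::optimize(obj, c(sigmas[i - 1L], sigmas[i + 1L]))
    if (opt$objective <= ss[i]) sigma_hat <- opt$minimum
  }
  pred <- predict_bias_curve(bimodal_prior(sigma_hat), lik,
                             obs$stimulus_deg, grid_step_deg)$bias_deg
  resid <- obs$bias_deg - pred
  ss_res <- sum(resid^2)
  ss_tot <- sum((obs$bias_deg - mean(obs$bias_deg))^2)
  ss_zero <- sum(obs$bias_deg^2)
  structure(
    list(sigma_prior_hat_deg = sigma_hat,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
         r_squared_zero = if (ss_zero > 0) 1 - ss_res / ss_zero else 0,
         residuals_deg = resid,
         boundary = boundary),
    class = "sigma_fit"
  )
}

#' @export
print.sigma_fit <- function(x, ...) {
  cat(sprintf("Bimodal-prior fit: sigma_prior %.2f deg, R^2 %.3f%s\n",
              x$sigma_prior_hat_deg, x$r_squared,
              if (x$boundary) " (search-range boundary)" else ""))
  invisible(x)
}
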