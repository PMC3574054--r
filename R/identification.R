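#' Chauvenet outlier exclusion for repeated heading responses
#'
#' Single-pass circular Chauvenet rule: responses deviating by more than
#' `k` circular standard deviations from the circular mean of all
#' presentations are excluded (default `k = 2.4`). The mean and SD are
#' computed once from the full sample; exclusion is not iterated.
#'
#' @param angles_deg numeric vector of at least 3 response angles (deg).
#' @param k SD multiplier.
#' @return list with numeric vectors `kept` and `excluded` (original
#'   values, order preserved) and logical vector `is_excluded`.
#' @examples
#' chauvenet_filter(c(0, 1, -1, 2, -2, 1, 0, -1, 1, 120))$excluded # 120
#' @export
chauvenet_filter <- function(angles_deg, k = 2.4) {
  if (length(angles_deg) < 3) {
    stop("chauvenet_filter(): need at least 3 angles", call. = FALSE)
  }
  m <- circular_mean_deg(angles_deg)
  s <- circular_sd_deg(angles_deg)
  dev <- abs(wrap_angle(angles_deg - m))
  out <- dev > k * s
  list(kept = angles_deg[!out], excluded = angles_deg[out], is_excluded = out)
}

#' Per-heading bias and variability from an identification log
#'
#' For each presented heading: apply [chauvenet_filter()] (when at least 3
#' responses are available), then compute the circular mean response, the
#' signed bias `wrap(mean response - stimulus)`, and the circular SD of the
#' kept responses. Headings whose responses all cancel (degenerate circular
#' mean) are flagged with `NA` rather than dropped.
#'
#' @param log data.frame with columns `stimulus_deg`, `response_deg` (as
#'   written by [simulate_identification()]).
#' @param chauvenet_k SD multiplier for outlier exclusion; `NULL` disables
#'   exclusion.
#' @return a `bias_curve`: data.frame ordered by stimulus angle with
#'   columns `stimulus_deg`, `mean_response_deg`, `bias_deg`,
#'   `circ_sd_deg`, `n_kept`, `n_excluded`.
#' @export
summarize_identification <- function(log, chauvenet_k = 2.4) {
  stopifnot(is.data.frame(log),
            all(c("stimulus_deg", "response_deg") %in% names(log)))
  if (nrow(log) == 0L) {
    stop("summarize_identification(): empty trial log", call. = FALSE)
  }
  stim <- wrap_angle(log$stimulus_deg)
  groups <- split(log$response_deg, stim)
  entries <- lapply(names(groups), function(key) {
    theta <- as.numeric(key)
    resp <- groups[[key]]
    if (!is.null(chauvenet_k) && length(resp) >= 3) {
      flt <- chauvenet_filter(resp, k = chauvenet_k)
      kept <- flt$kept
      n_exc <- length(flt$excluded)
    } else {
      kept <- resp
      n_exc <- 0L
    }
    mean_resp <- tryCatch(circular_mean_deg(kept), error = function(e) NA_real_)
    data.frame(
      stimulus_deg = theta,
      mean_response_deg = mean_resp,
      bias_deg = if (is.na(mean_resp)) NA_real_ else wrap_angle(mean_resp - theta),
      circ_sd_deg = if (length(kept)) circular_sd_deg(kept) else NA_real_,
      n_kept = length(kept),
      n_excluded = n_exc
    )
  })
  curve <- do.call(rbind, entries)
  curve <- curve[order(curve$stimulus_deg), , drop = FALSE]
  rownames(curve) <- NULL
  structure(curve, class = c("bias_curve", "data.frame"))
}

#' Construct a bias curve directly
#'
#' Convenience constructor used for model-generated or externally supplied
#' bias curves.
#'
#' @param stimulus_deg heading angles (deg).
#' @param bias_deg signed biases (deg).
#' @param circ_sd_deg optional per-heading variability (deg).
#' @return a `bias_curve` data.frame.
#' @export
bias_curve <- function(stimulus_deg, bias_deg, circ_sd_deg = NA_real_) {
  stopifnot(length(stimulus_deg) == length(bias_deg))
  stim <- wrap_angle(stimulus_deg)
  if (anyDuplicated(stim)) {
    stop("bias_curve(): duplicate stimulus angles", call. = FALSE)
  }
  df <- data.frame(
    stimulus_deg = stim,
    mean_response_deg = wrap_angle(stim + bias_deg),
    bias_deg = wrap_angle(bias_deg),
    circ_sd_deg = rep_len(circ_sd_deg, length(stim)),
    n_kept = NA_integer_, n_excluded = NA_integer_
  )
  df <- df[order(df$stimulus_deg), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("bias_curve", "data.frame"))
}

#' Polynomial interpolation of the stimulus-response curve
#'
#' Fits a degree-12 polynomial (by least squares) to the unwrapped
#' stimulus-response relation of a bias curve, mirroring the interpolation
#' used to read identification-task responses at arbitrary physical
#' stimuli. Responses are first unwrapped onto the identity line
#' (`response = stimulus + wrapped bias`) so the fit never sees the 360
#' degree discontinuity; stimulus angles are scaled to `[-1, 1]` before the
#' Vandermonde fit for conditioning. Evaluation is restricted to the fitted
#' stimulus range; extrapolation is an error.
#'
#' @param curve a `bias_curve` (NA entries are dropped).
#' @param degree polynomial degree (default 12).
#' @return object of class `response_curve_fit` with fields
#'   `coefficients` (on the scaled basis), `scale_deg`, `domain_deg`,
#'   `degree`, `rmse_deg`.
#' @export
fit_response_curve <- function(curve, degree = 12) {
  stopifnot(inherits(curve, "data.frame"))
  ok <- is.finite(curve$stimulus_deg) & is.finite(curve$bias_deg)
  x <- wrap_angle(curve$stimulus_deg[ok])
  y <- x + wrap_angle(curve$bias_deg[ok]) # unwrapped response near identity
  if (length(unique(x)) < degree + 1) {
    stop("fit_response_curve(): need at least degree + 1 distinct headings",
         call. = FALSE)
  }
  scale <- max(abs(x))
  z <- x / scale
  fit <- stats::lm.fit(outer(z, 0:degree, `^`), y)
  structure(
    list(coefficients = unname(fit$coefficients),
         scale_deg = scale,
         domain_deg = range(x),
         degree = degree,
         rmse_deg = sqrt(mean(fit$residuals^2))),
    class = "response_curve_fit"
  )
}

#' Evaluate a fitted response curve
#'
#' @param fit a [fit_response_curve()] object.
#' @param physical_deg stimulus angle(s) inside the fitted domain.
#' @return predicted (unwrapped) response in degrees.
#' @export
predict_response <- function(fit, physical_deg) {
  stopifnot(inherits(fit, "response_curve_fit"))
  theta <- wrap_angle(physical_deg)
  if (any(theta < fit$domain_deg[1] - 1e-9 | theta > fit$domain_deg[2] + 1e-9)) {
    stop(sprintf(
      "predict_response(): stimulus outside fitted domain [%.1f, %.1f]",
      fit$domain_deg[1], fit$domain_deg[2]), call. = FALSE)
  }
  drop(outer(theta / fit$scale_deg, 0:fit$degree, `^`) %*% fit$coefficients)
}

#' Identification bias at a physical stimulus
#'
#' Reads the interpolated identification bias at an arbitrary physical
#' heading, the quantity paired with discrimination-task PSEs for
#' subject-by-subject cross-task comparison.
#'
#' @inheritParams predict_response
#' @return signed bias `wrap(fit(physical) - physical)` in degrees.
#' @export
bias_at_physical <- function(fit, physical_deg) {
  wrap_angle(predict_response(fit, physical_deg) - wrap_angle(physical_deg))
}
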