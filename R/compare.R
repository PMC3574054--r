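#' Spearman rank correlation between paired bias sets
#'
#' Rank correlation (average ranks on ties) with a two-sided p-value from
#' the large-sample approximation, as used to compare bias values across
#' tasks and modalities. Headings that are unbiased by symmetry (0 and
#' 180 deg) are conventionally excluded by the caller before pairing.
#'
#' @param x,y paired bias values (deg), equal length >= 5.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) {
    stop("spearman_rho(): need at least 5 pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_rho(): correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Type II regression slope
#'
#' Errors-in-both-variables regression slope for bias-versus-bias
#' comparisons. The default standardized major axis (SMA) slope is
#' `sign(r) * SD(y)/SD(x)`, symmetric under exchange of axes (the slope
#' inverts to its reciprocal); the major-axis (MA) variant is available by
#' flag.
#'
#' @param x,y paired values, equal length >= 3.
#' @param method `"sma"` (standardized major axis) or `"ma"` (major axis).
#' @return slope estimate.
#' @export
type2_slope <- function(x, y, method = c("sma", "ma")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    stop("type2_slope(): need at least 3 pairs", call. = FALSE)
  }
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0) {
    stop("type2_slope(): zero variance in x; slope undefined", call. = FALSE)
  }
  if (sy == 0) {
    stop("type2_slope(): zero variance in y; slope undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (method == "sma") {
    sign_r <- if (r < 0) -1 else 1
    sign_r * sy / sx
  } else {
    sxy <- stats::cov(x, y)
    if (sxy == 0) {
      return(if (sy > sx) Inf else 0) # vertical / horizontal major axis
    }
    (sy^2 - sx^2 + sqrt((sy^2 - sx^2)^2 + 4 * sxy^2)) / (2 * sxy)
  }
}

#' Coefficient of determination against an external prediction
#'
#' `R^2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, computed
#' about the observed mean (the `about = "zero"` variant normalizes by the
#' raw sum of squares instead). Negative values indicate the prediction
#' does worse than the observed mean, as happens when a parameter-free
#' model gets the shape right but overshoots the magnitude.
#'
#' @param observed,predicted equal-length numeric vectors (>= 2).
#' @param about `"mean"` or `"zero"`.
#' @return R-squared (may be negative; 1 iff the prediction is exact).
#' @export
r2_vs_prediction <- function(observed, predicted, about = c("mean", "zero")) {
  about <- match.arg(about)
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2) {
    stop("r2_vs_prediction(): need at least 2 values", call. = FALSE)
  }
  center <- if (about == "mean") mean(observed) else 0
  ss_tot <- sum((observed - center)^2)
  if (ss_tot == 0) {
    stop("r2_vs_prediction(): zero total sum of squares; R^2 undefined",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Compare two bias curves
#'
#' Joins two bias curves on stimulus angle (optionally excluding the
#' unbiased 0 and 180 deg headings) and reports the Spearman correlation,
#' type II regression slope, and R-squared of curve `b` as a prediction of
#' curve `a`.
#'
#' @param a,b `bias_curve` data.frames.
#' @param exclude_cardinal drop 0 and 180 deg before comparing.
#' @return list with `rho`, `p_value`, `slope`, `r_squared`, `n`.
#' @export
compare_bias_curves <- function(a, b, exclude_cardinal = TRUE) {
  m <- merge(a[, c("stimulus_deg", "bias_deg")],
             b[, c("stimulus_deg", "bias_deg")],
             by = "stimulus_deg", suffixes = c("_a", "_b"))
  if (exclude_cardinal) {
    m <- m[!(abs(m$stimulus_deg) < 1e-9 | abs(abs(m$stimulus_deg) - 180) < 1e-9), ]
  }
  m <- m[is.finite(m$bias_deg_a) & is.finite(m$bias_deg_b), ]
  sp <- spearman_rho(m$bias_deg_a, m$bias_deg_b)
  list(rho = sp$rho, p_value = sp$p_value,
       slope = type2_slope(m$bias_deg_a, m$bias_deg_b),
       r_squared = r2_vs_prediction(m$bias_deg_a, m$bias_deg_b),
       n = nrow(m))
}
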