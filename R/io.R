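# File-format plumbing. All angle columns are serialized in degrees with 3
# decimal places; CSVs carry a header row, UTF-8, "." decimal separator.

round3 <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], 3)
  df
}

#' Read and write identification trial logs
#'
#' CSV dialect: columns `subject`, `block`, `presentation`, `stimulus_deg`,
#' `response_deg`.
#'
#' @param log identification trial log data.frame.
#' @param path file path.
#' @return `read_identification_log` returns the trial log data.frame;
#'   the writer returns `path` invisibly.
#' @export
write_identification_log <- function(log, path) {
  stopifnot(all(c("subject", "block", "presentation",
                  "stimulus_deg", "response_deg") %in% names(log)))
  utils::write.csv(round3(log, c("stimulus_deg", "response_deg")), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_identification_log
#' @export
read_identification_log <- function(path) {
  log <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("subject", "block", "presentation", "stimulus_deg", "response_deg")
  if (!all(need %in% names(log))) {
    stop("read_identification_log(): missing columns: ",
         paste(setdiff(need, names(log)), collapse = ", "), call. = FALSE)
  }
  log
}

#' Read and write 2AFC staircase logs
#'
#' CSV dialect: columns `subject`, `block`, `investigated_deg`, `trial`,
#' `stimulus_deg`, `response_cw` (0/1), `staircase_id`, `reversal` (0/1).
#'
#' @param blocks a `staircase_block`, or list of them; `subject`/`block`
#'   labels are attached per block.
#' @param path file path.
#' @param subject subject label.
#' @return the writer returns `path` invisibly; the reader returns the
#'   trial data.frame.
#' @export
write_staircase_log <- function(blocks, path, subject = "s01") {
  if (inherits(blocks, "staircase_block")) blocks <- list(blocks)
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(subject = subject, block = i,
               investigated_deg = b$investigated_deg,
               trial = b$trials$trial, stimulus_deg = b$trials$stimulus_deg,
               response_cw = b$trials$response_cw,
               staircase_id = b$trials$staircase_id,
               reversal = b$trials$reversal)
  })
  df <- round3(do.call(rbind, rows), c("investigated_deg", "stimulus_deg"))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_staircase_log
#' @export
read_staircase_log <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("subject", "block", "investigated_deg", "trial", "stimulus_deg",
            "response_cw", "staircase_id", "reversal")
  if (!all(need %in% names(df))) {
    stop("read_staircase_log(): missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read and write per-heading bias curves
#'
#' CSV dialect: columns `stimulus_deg`, `bias_deg`, `circ_sd_deg`,
#' `n_kept`, `n_excluded`.
#'
#' @param curve a `bias_curve` data.frame.
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader a `bias_curve`.
#' @export
write_bias_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  for (cl in c("circ_sd_deg", "n_kept", "n_excluded")) {
    if (is.null(df[[cl]])) df[[cl]] <- NA
  }
  df <- round3(df[, c("stimulus_deg", "bias_deg", "circ_sd_deg",
                      "n_kept", "n_excluded")],
               c("stimulus_deg", "bias_deg", "circ_sd_deg"))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_bias_curve
#' @export
read_bias_curve <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("stimulus_deg", "bias_deg") %in% names(df))) {
    stop("read_bias_curve(): missing stimulus_deg/bias_deg columns", call. = FALSE)
  }
  out <- bias_curve(df$stimulus_deg, df$bias_deg,
                    if ("circ_sd_deg" %in% names(df)) df$circ_sd_deg else NA_real_)
  if ("n_kept" %in% names(df)) out$n_kept <- df$n_kept
  if ("n_excluded" %in% names(df)) out$n_excluded <- df$n_excluded
  out
}

#' Read and write neural populations
#'
#' CSV dialect: columns `azimuth_deg`, `elevation_deg`, `sensitivity`,
#' `resting_discharge`. Laterality is not part of the on-disk format and
#' is supplied by the reader.
#'
#' @param pop a `neural_population`.
#' @param path file path.
#' @param laterality laterality label attached on read.
#' @return the writer returns `path` invisibly; the reader a
#'   `neural_population`.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "neural_population"))
  utils::write.csv(round3(as.data.frame(pop),
                          c("azimuth_deg", "elevation_deg")),
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path, laterality = "bilateral") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("azimuth_deg", "elevation_deg", "sensitivity", "resting_discharge")
  if (!all(need %in% names(df))) {
    stop("read_population(): missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  neurons(df$azimuth_deg, df$elevation_deg, df$sensitivity,
          df$resting_discharge, laterality = laterality)
}

#' Read and write likelihood profiles (YAML)
#'
#' The YAML schema is a `nodes` list of `{heading_deg, sd_deg}` maps.
#'
#' @param profile a [likelihood_profile()].
#' @param path file path.
#' @return the writer returns `path` invisibly; the reader a
#'   `likelihood_profile`.
#' @export
write_likelihood_profile <- function(profile, path) {
  stopifnot(inherits(profile, "likelihood_profile"))
  nodes <- lapply(seq_len(nrow(profile$nodes)), function(i) {
    list(heading_deg = profile$nodes$heading_deg[i],
         sd_deg = profile$nodes$sd_deg[i])
  })
  yaml::write_yaml(list(nodes = nodes), path)
  invisible(path)
}

#' @rdname write_likelihood_profile
#' @export
read_likelihood_profile <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("bayes_observer: profile not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$nodes)) {
    stop("read_likelihood_profile(): YAML must contain a 'nodes' list", call. = FALSE)
  }
  nodes <- do.call(rbind, lapply(raw$nodes, function(nd) {
    data.frame(heading_deg = nd$heading_deg, sd_deg = nd$sd_deg)
  }))
  likelihood_profile(nodes)
}

#' Write a fit record as JSON
#'
#' Serializes a [fit_response_curve()], [fit_sigma_prior()] or
#' [fit_cumulative_gaussian()] result (or any named list of scalars and
#' vectors) to JSON.
#'
#' @param fit list-like fit object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
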