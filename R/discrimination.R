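#' Transformed up-down staircase rule
#'
#' A staircase rule raises the stimulus after `n_up` consecutive
#' "counter-clockwise" (stimulus-less-than-reference) responses and lowers
#' it after `n_down` consecutive "clockwise" responses, always by
#' `step_deg`. The classical rules and their asymptotic convergence points
#' on the psychometric function P(clockwise):
#' 1U1D -> 50%, 2U1D -> 29.3%, 1U2D -> 70.7%.
#'
#' @param rule one of `"1U1D"`, `"2U1D"`, `"1U2D"`, or `NULL` to give
#'   `n_up`/`n_down` directly.
#' @param step_deg step size in degrees (default 4, the laboratory value).
#' @param n_up,n_down consecutive-response counts (each 1 or 2).
#' @return object of class `staircase_rule`.
#' @export
staircase_rule <- function(rule = c("1U1D", "2U1D", "1U2D"), step_deg = 4,
                           n_up = NULL, n_down = NULL) {
  if (is.null(n_up) || is.null(n_down)) {
    rule <- match.arg(rule)
    n_up <- switch(rule, "1U1D" = 1L, "2U1D" = 2L, "1U2D" = 1L)
    n_down <- switch(rule, "1U1D" = 1L, "2U1D" = 1L, "1U2D" = 2L)
  } else {
    rule <- sprintf("%dU%dD", n_up, n_down)
  }
  if (!n_up %in% 1:2 || !n_down %in% 1:2) {
    stop("staircase_rule(): n_up and n_down must be 1 or 2", call. = FALSE)
  }
  if (step_deg <= 0) {
    stop("staircase_rule(): step_deg must be positive", call. = FALSE)
  }
  structure(list(name = rule, n_up = as.integer(n_up),
                 n_down = as.integer(n_down), step_deg = step_deg),
            class = "staircase_rule")
}

#' Single staircase update
#'
#' Given the responses observed since the last step (most recent last),
#' returns the next stimulus level: `+step` after `n_up` consecutive
#' counter-clockwise responses, `-step` after `n_down` consecutive
#' clockwise responses, otherwise unchanged. Consecutive-response counters
#' are implicitly reset after each step because the caller passes only the
#' responses since that step.
#'
#' @param rule a [staircase_rule()].
#' @param current_deg current stimulus level (deg).
#' @param recent_responses 0/1 (or logical) responses since the last step,
#'   1 = clockwise ("stimulus greater than reference").
#' @return next stimulus level in degrees.
#' @export
staircase_update <- function(rule, current_deg, recent_responses) {
  stopifnot(inherits(rule, "staircase_rule"), length(recent_responses) >= 1)
  r <- as.integer(recent_responses)
  last <- r[length(r)]
  run <- 1L
  while (run < length(r) && r[length(r) - run] == last) run <- run + 1L
  if (last == 0L && run >= rule$n_up) {
    current_deg + rule$step_deg
  } else if (last == 1L && run >= rule$n_down) {
    current_deg - rule$step_deg
  } else {
    current_deg
  }
}

#' Run one interleaved staircase block against a simulated observer
#'
#' Runs two staircases of the same rule, strictly alternating trial by
#' trial: a descending staircase starting at
#' `investigated + start_offset_deg` and an ascending one starting at
#' `investigated - start_offset_deg` (offsets of +/-26 deg for the 35-trial
#' 1U1D blocks, +/-18 deg for the 40-trial 2U1D/1U2D blocks in the
#' laboratory protocol). Stimulus levels are tracked on the unwrapped real
#' line so that blocks near +/-180 deg are not corrupted by wrapping; the
#' observer's response probability uses the wrapped stimulus-PSE
#' difference. A trial is flagged as a reversal when the step it triggers
#' is opposite in direction to the staircase's previous step.
#'
#' @param observer an [afc_observer()].
#' @param investigated_deg reference heading for the block (deg).
#' @param rule a [staircase_rule()].
#' @param n_trials trials per staircase (>= 10).
#' @param start_offset_deg magnitude of the starting offsets (deg).
#' @param seed integer seed.
#' @return object of class `staircase_block`: list with the inputs plus
#'   `trials`, a data.frame with columns `trial`, `staircase_id`
#'   (1 = descending, 2 = ascending), `stimulus_deg`, `response_cw`,
#'   `reversal`.
#' @export
run_block <- function(observer, investigated_deg, rule, n_trials = 35,
                      start_offset_deg = 26, seed = 1) {
  stopifnot(inherits(observer, "afc_observer"), inherits(rule, "staircase_rule"))
  if (n_trials < 10) {
    stop("run_block(): need at least 10 trials per staircase", call. = FALSE)
  }
  levels0 <- investigated_deg + c(start_offset_deg, -start_offset_deg)
  trials <- with_local_seed(seed, {
    n_tot <- 2L * n_trials
    level <- levels0
    since_step <- list(integer(0), integer(0))
    last_dir <- c(0, 0)
    stim_v <- resp_v <- rev_v <- numeric(n_tot)
    sc_v <- integer(n_tot)
    u <- stats::runif(n_tot) # one draw per trial, in trial order
    for (t in seq_len(n_tot)) {
      sc <- if (t %% 2L == 1L) 1L else 2L
      stim <- level[sc]
      resp <- as.integer(u[t] < prob_clockwise(observer, stim))
      since_step[[sc]] <- c(since_step[[sc]], resp)
      nxt <- staircase_update(rule, stim, since_step[[sc]])
      step_dir <- sign(nxt - stim)
      reversal <- step_dir != 0 && last_dir[sc] != 0 && step_dir != last_dir[sc]
      if (step_dir != 0) {
        since_step[[sc]] <- integer(0)
        last_dir[sc] <- step_dir
      }
      sc_v[t] <- sc
      stim_v[t] <- stim
      resp_v[t] <- resp
      rev_v[t] <- as.integer(reversal)
      level[sc] <- nxt
    }
    data.frame(trial = seq_len(n_tot), staircase_id = sc_v,
               stimulus_deg = stim_v, response_cw = resp_v,
               reversal = rev_v)
  })
  structure(
    list(investigated_deg = investigated_deg, rule = rule,
         n_trials = as.integer(n_trials),
         start_offset_deg = start_offset_deg, seed = seed, trials = trials),
    class = "staircase_block"
  )
}

#' PSE estimate from staircase reversals
#'
#' Arithmetic mean of the reversal stimulus levels, discarding the first
#' `n_ignore` reversals of each staircase (the classical
#' average-of-reversals estimator). Accepts either a [run_block()] result
#' or a plain numeric vector of reversal levels from a single staircase.
#'
#' @param block a `staircase_block`, or numeric reversal levels.
#' @param n_ignore reversals to discard per staircase (default 4).
#' @return PSE estimate in degrees, wrapped to `(-180, 180]`.
#' @export
pse_from_reversals <- function(block, n_ignore = 4) {
  if (is.numeric(block)) {
    revs <- list(block)
  } else {
    stopifnot(inherits(block, "staircase_block"))
    tr <- block$trials
    revs <- lapply(split(tr, tr$staircase_id), function(d) {
      d$stimulus_deg[d$reversal == 1]
    })
  }
  kept <- unlist(lapply(revs, function(v) {
    if (length(v) > n_ignore) v[-seq_len(n_ignore)] else numeric(0)
  }))
  n_rev <- sum(lengths(revs))
  if (n_rev < n_ignore + 2 || length(kept) < 2) {
    stop(sprintf(
      "pse_from_reversals(): too few reversals (%d) for a stable estimate",
      n_rev), call. = FALSE)
  }
  wrap_angle(mean(kept))
}

#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `P(clockwise | x) = lapse + (1 - 2*lapse) * Phi((x - PSE)/JND)` to
#' binomial response counts by maximum likelihood. With the default
#' `lapse = 0` this is an exact probit GLM; a fixed small lapse (e.g. 0.01)
#' is available as a robustness switch and is fitted by direct likelihood
#' maximization.
#'
#' @param levels_deg distinct stimulus levels (deg); at least 3, spanning
#'   both response categories.
#' @param n_cw number of clockwise responses per level (expected counts are
#'   accepted, so exact-probability data can be fitted).
#' @param n_total number of trials per level.
#' @param lapse fixed lapse/guess rate in `[0, 0.25)`.
#' @return object of class `psychometric_fit`: list with `pse_deg`,
#'   `jnd_deg`, `n_trials_used`, `lapse`, `converged`.
#' @export
fit_cumulative_gaussian <- function(levels_deg, n_cw, n_total, lapse = 0) {
  stopifnot(length(levels_deg) == length(n_cw),
            length(levels_deg) == length(n_total))
  if (any(n_total <= 0) || any(n_cw < 0) || any(n_cw > n_total)) {
    stop("fit_cumulative_gaussian(): invalid counts", call. = FALSE)
  }
  if (length(unique(levels_deg)) < 3) {
    stop("fit_cumulative_gaussian(): need at least 3 distinct levels",
         call. = FALSE)
  }
  if (sum(n_cw) == 0 || sum(n_total - n_cw) == 0) {
    stop("fit_cumulative_gaussian(): responses do not span both categories; fit is non-identifiable",
         call. = FALSE)
  }
  if (lapse < 0 || lapse >= 0.25) {
    stop("fit_cumulative_gaussian(): lapse must lie in [0, 0.25)", call. = FALSE)
  }
  if (lapse == 0) {
    prop <- n_cw / n_total
    fit <- suppressWarnings(stats::glm(
      prop ~ levels_deg, weights = n_total,
      family = stats::binomial(link = "probit")
    ))
    b <- stats::coef(fit)
    if (!all(is.finite(b)) || b[2] <= 0) {
      stop("fit_cumulative_gaussian(): degenerate fit (non-positive or infinite slope)",
           call. = FALSE)
    }
    pse <- -b[[1]] / b[[2]]
    jnd <- 1 / b[[2]]
    conv <- fit$converged
  } else {
    nll <- function(par) {
      p <- lapse + (1 - 2 * lapse) *
        stats::pnorm((levels_deg - par[1]) / exp(par[2]))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(n_cw * log(p) + (n_total - n_cw) * log(1 - p))
    }
    start <- c(stats::weighted.mean(levels_deg, n_total),
               log(max(stats::sd(rep(levels_deg, n_total)), 1)))
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    pse <- opt$par[1]
    jnd <- exp(opt$par[2])
    conv <- opt$convergence == 0
  }
  structure(list(pse_deg = unname(pse), jnd_deg = unname(jnd),
                 n_trials_used = sum(n_total), lapse = lapse,
                 converged = conv),
            class = "psychometric_fit")
}

#' Psychometric fit from staircase blocks
#'
#' Aggregates the trial logs of one or more staircase blocks for the same
#' investigated direction into per-level binomial counts and fits the
#' cumulative Gaussian, the route used to obtain the PSE and JND for each
#' investigated heading.
#'
#' @param blocks a `staircase_block` or list of them.
#' @param lapse fixed lapse rate passed to [fit_cumulative_gaussian()].
#' @return a `psychometric_fit`.
#' @export
fit_block_psychometric <- function(blocks, lapse = 0) {
  if (inherits(blocks, "staircase_block")) blocks <- list(blocks)
  tr <- do.call(rbind, lapply(blocks, function(b) b$trials))
  n_cw <- tapply(tr$response_cw, tr$stimulus_deg, sum)
  n_total <- tapply(tr$response_cw, tr$stimulus_deg, length)
  fit_cumulative_gaussian(as.numeric(names(n_cw)), as.numeric(n_cw),
                          as.numeric(n_total), lapse = lapse)
}

#' Discrimination-task bias
#'
#' Signed bias of the discrimination task: `wrap(investigated - PSE)`. A
#' PSE of -75 deg for investigated direction -90 deg gives a bias of
#' -15 deg, i.e. a 15 deg overestimation of heading eccentricity.
#'
#' @param investigated_deg investigated (reference) heading, deg.
#' @param pse_deg fitted PSE, deg.
#' @return signed bias in degrees on `(-180, 180]`.
#' @export
discrimination_bias <- function(investigated_deg, pse_deg) {
  wrap_angle(investigated_deg - pse_deg)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("Cumulative-Gaussian fit: PSE %.2f deg, JND %.2f deg (%d trials)\n",
              x$pse_deg, x$jnd_deg, x$n_trials_used))
  invisible(x)
}
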