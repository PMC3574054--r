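test_that("staircase update rules follow the transformed up-down logic", {
  r11 <- staircase_rule("1U1D")
  expect_equal(staircase_update(r11, 10, 1), 6)  # "greater" -> down 4 deg
  expect_equal(staircase_update(r11, 10, 0), 14)
  r21 <- staircase_rule("2U1D")
  expect_equal(staircase_update(r21, 10, 0), 10)        # single "less": no step
  expect_equal(staircase_update(r21, 10, c(0, 0)), 14)  # two consecutive "less"
  expect_equal(staircase_update(r21, 10, c(0, 1)), 6)   # single "greater" steps down
  r12 <- staircase_rule("1U2D")
  expect_equal(staircase_update(r12, 10, c(1, 1)), 6)
  expect_equal(staircase_update(r12, 10, 1), 10)
  expect_error(staircase_rule(step_deg = 0), "step")
})

test_that("blocks are reproducible and a near-deterministic observer descends monotonically then oscillates", {
  obs <- afc_observer(-90, 8)
  b1 <- run_block(obs, -90, staircase_rule("1U1D"), 35, 26, seed = 42)
  expect_identical(b1, run_block(obs, -90, staircase_rule("1U1D"), 35, 26, seed = 42))
  expect_equal(nrow(b1$trials), 70)
  expect_equal(as.integer(table(b1$trials$staircase_id)), c(35L, 35L))
  # jnd -> 0: descent from +26 at one step per trial, then +-2 oscillation
  od <- afc_observer(0, 1e-9)
  bd <- run_block(od, 0, staircase_rule("1U1D"), 20, 26, seed = 1)
  lv <- bd$trials$stimulus_deg[bd$trials$staircase_id == 1]
  expect_equal(lv[1:8], seq(26, -2, by = -4))
  expect_equal(lv[9:20], rep(c(2, -2), 6))
})

test_that("staircases converge near the investigated direction", {
  obs <- afc_observer(-90, 8)
  fin <- t(vapply(1:200, function(i) {
    b <- run_block(obs, -90, staircase_rule("1U1D"), 35, 26, seed = i)
    tapply(b$trials$stimulus_deg, b$trials$staircase_id,
           function(v) v[length(v)])
  }, numeric(2)))
  # final levels within two 4-deg steps of the investigated direction
  expect_gte(mean(abs(fin + 90) <= 8), 0.9)
})

test_that("reversal averaging estimates the PSE", {
  # discarding the first four of [10,-2,2,-2,2,-2,2] keeps [2,-2,2]
  expect_equal(pse_from_reversals(c(10, -2, 2, -2, 2, -2, 2)),
               mean(c(2, -2, 2)), tolerance = 1e-12)
  expect_error(pse_from_reversals(c(1, 2, 3)), "too few reversals")
  # noiseless oscillation around 0: estimate within half a step
  od <- afc_observer(0, 1e-9)
  bd <- run_block(od, 0, staircase_rule("1U1D"), 35, 26, seed = 2)
  expect_lt(abs(pse_from_reversals(bd)), 2)
  # Monte-Carlo: 500 blocks against pse -90, jnd 8
  est <- vapply(1:500, function(i) {
    pse_from_reversals(run_block(afc_observer(-90, 8), -90,
                                 staircase_rule("1U1D"), 35, 26,
                                 seed = 1000 + i))
  }, numeric(1))
  expect_equal(mean(est), -90, tolerance = 1 / 90)
})

test_that("the cumulative-Gaussian fit recovers exact and simulated psychometric data", {
  # exact probabilities at 5 levels reproduce the generating PSE/JND to 1e-4
  lv <- c(-20, -10, 0, 10, 20)
  p <- pnorm((lv - 3) / 7)
  fit <- fit_cumulative_gaussian(lv, p * 1000, rep(1000, 5))
  expect_equal(fit$pse_deg, 3, tolerance = 1e-4)
  expect_equal(fit$jnd_deg, 7, tolerance = 1e-4)
  # mirrored data: PSE negates, JND unchanged
  fitm <- fit_cumulative_gaussian(-lv, (1 - p) * 1000, rep(1000, 5))
  expect_equal(fitm$pse_deg, -3, tolerance = 1e-4)
  expect_equal(fitm$jnd_deg, 7, tolerance = 1e-4)
  expect_error(fit_cumulative_gaussian(lv, rep(0, 5), rep(10, 5)),
               "non-identifiable")
  expect_error(fit_cumulative_gaussian(c(0, 1), c(0, 1), c(1, 1)), "distinct")
})

test_that("the worked discrimination scenario recovers PSE -75 and JND 8.42", {
  res <- t(vapply(1:200, function(i) {
    o <- afc_observer(-75, 8.42)
    b1 <- run_block(o, -90, staircase_rule("1U1D"), 35, 26, seed = i * 31)
    p1 <- pse_from_reversals(b1)
    b2 <- run_block(o, p1, staircase_rule("2U1D"), 40, 18, seed = i * 31 + 1)
    b3 <- run_block(o, p1, staircase_rule("1U2D"), 40, 18, seed = i * 31 + 2)
    f <- fit_block_psychometric(list(b1, b2, b3))
    c(f$pse_deg, f$jnd_deg, p1)
  }, numeric(3)))
  expect_equal(mean(res[, 1]), -75, tolerance = 2 / 75)
  expect_equal(mean(res[, 2]), 8.42, tolerance = 2 / 8.42)
  # JND recovery unbiased within 15% at ~150 trials
  expect_lt(abs(mean(res[, 2]) - 8.42) / 8.42, 0.15)
  # reversal and psychometric PSE estimates agree in expectation within 1 deg
  expect_lt(abs(mean(res[, 3]) - mean(res[, 1])), 1)
})

test_that("discrimination bias is the wrapped investigated-minus-PSE difference", {
  expect_equal(discrimination_bias(-90, -75), -15)
  expect_equal(discrimination_bias(45, 45), 0)
  expect_equal(discrimination_bias(180, -175), -5)
})
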