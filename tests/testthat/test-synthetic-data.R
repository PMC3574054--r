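test_that("identification trial logs are reproducible and stay in the canonical range", {
  obs <- id_observer(noise_sd_deg = 20, lapse_rate = 0.05)
  des <- identification_design()
  a <- simulate_identification(obs, des, seed = 11)
  b <- simulate_identification(obs, des, seed = 11)
  expect_identical(a, b)
  c <- simulate_identification(obs, des, seed = 12)
  expect_false(identical(a$response_deg, c$response_deg))
  expect_true(all(a$response_deg > -180 & a$response_deg <= 180))
  expect_equal(nrow(a), 480)
  # every heading appears exactly n_blocks * reps times
  expect_true(all(table(a$stimulus_deg) == 10))
})

test_that("an unbiased quiet observer produces near-zero per-heading mean bias", {
  obs <- id_observer(bias_fn = function(th) rep(0, length(th)),
                     noise_sd_fn = function(th) rep(0.01, length(th)))
  log <- simulate_identification(obs, identification_design(), seed = 3)
  cv <- summarize_identification(log, chauvenet_k = NULL)
  expect_true(all(abs(cv$bias_deg) < 0.05))
})

test_that("the generating lateral bias is recovered from simulated logs", {
  # 6 sin(2 theta): peaks +6 near 45, -6 near 135; mean over 200 seeds
  obs <- id_observer(noise_sd_deg = 5)
  des <- identification_design()
  b <- vapply(1:200, function(i) {
    cv <- summarize_identification(simulate_identification(obs, des, seed = i))
    c(cv$bias_deg[cv$stimulus_deg == 45], cv$bias_deg[cv$stimulus_deg == 135])
  }, numeric(2))
  expect_equal(mean(b[1, ]), 6, tolerance = 1.5 / 6) # +-1.5 deg
  expect_equal(mean(b[2, ]), -6, tolerance = 1.5 / 6)
})

test_that("2AFC responses follow the cumulative-Gaussian rule", {
  obs <- afc_observer(-75, 8.42)
  expect_equal(prob_clockwise(obs, -75), 0.5)
  expect_equal(prob_clockwise(obs, -75 + 8.42), pnorm(1))
  # Monte-Carlo at pse - jnd: fraction clockwise ~ Phi(-1) = 0.159
  set.seed(5)
  frac <- mean(respond_2afc(obs, rep(-75 - 8.42, 10000)))
  expect_equal(frac, pnorm(-1), tolerance = 0.01 / pnorm(-1))
  # Kolmogorov distance over a staircase-like level range at 1e4 draws
  lv <- seq(-95, -55, by = 5)
  phat <- vapply(lv, function(x) mean(respond_2afc(obs, rep(x, 10000))),
                 numeric(1))
  expect_lt(max(abs(phat - prob_clockwise(obs, lv))), 0.02)
  expect_error(afc_observer(0, 0), "jnd")
})

test_that("afferent populations have the configured lateral azimuth mode and unit polarization", {
  pop <- make_afferent_population(313, seed = 21)
  expect_equal(nrow(pop), 313)
  expect_identical(population_laterality(pop), "left-only")
  P <- polarization_matrix(pop)
  expect_equal(sqrt(rowSums(P^2)), rep(1, 313), tolerance = 1e-9)
  # histogram mode within +-15 deg of the +50 peak
  hst <- hist(pop$azimuth_deg, breaks = seq(-180, 180, by = 10), plot = FALSE)
  expect_lt(abs(hst$mids[which.max(hst$counts)] - 50), 15)
  expect_true(all(pop$sensitivity > 0) && all(pop$resting_discharge >= 0))
  # determinism and single-neuron edge
  expect_identical(pop, make_afferent_population(313, seed = 21))
  expect_equal(nrow(make_afferent_population(1, seed = 2)), 1)
})

test_that("cosine populations are exactly mirror-symmetric, including the uniform limit", {
  pop <- make_cosine_population(400, seed = 8)
  expect_identical(population_laterality(pop), "bilateral")
  az <- sort(wrap_angle(pop$azimuth_deg))
  expect_equal(az, sort(wrap_angle(-pop$azimuth_deg)), tolerance = 1e-12)
  expect_identical(pop, make_cosine_population(400, seed = 8))
  expect_error(make_cosine_population(10, azimuth_peaks_deg = c(90, -45)),
               "mirror pair")
  # uniform special case decodes without bias (oracle: uniformity => unbiased)
  pu <- make_cosine_population(10000, azimuth_spread_deg = Inf, seed = 9)
  bc <- decode_bias_curve(pu, make_motion_profile(1, 0.13))
  expect_lt(max(abs(bc$bias_deg)), 1)
})
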