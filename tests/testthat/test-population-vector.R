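prof <- make_motion_profile(1, 0.13)

test_that("the linear afferent firing model follows d = s (F.P) + d0", {
  n <- neurons(0, 0, sensitivity = 35, resting_discharge = 90)
  expect_equal(afferent_rate(n, c(1, 0, 0)), 125)  # F.P = 1 g
  expect_equal(afferent_rate(n, c(0, 1, 0)), 90)   # F perpendicular to P
  expect_equal(afferent_rate(n, c(0, 0, -1)), 90)  # gravity orthogonal to horizontal P
  expect_equal(afferent_rate(n, c(-10, 0, 0), rectify = TRUE), 0)
})

test_that("peak-to-trough response cancels gravity and resting discharge", {
  # P aligned with the heading: 2 * s * a_peak_g
  n <- neurons(37, 0, sensitivity = 35, resting_discharge = 90)
  a_g <- prof$peak_accel_m_s2 / 9.80665
  expect_equal(peak_to_trough_response(n, prof, 37), 2 * 35 * a_g,
               tolerance = 1e-12)
  # vertical P: zero for every horizontal heading
  nv <- neurons(0, 90, 35, 90)
  for (th in c(0, 45, 90, 180)) {
    expect_equal(peak_to_trough_response(nv, prof, th), 0, tolerance = 1e-9)
  }
  # odd symmetry in heading
  nn <- neurons(c(30, -40), c(10, -20), c(35, 20), c(90, 80))
  expect_equal(peak_to_trough_response(nn, prof, 25),
               -peak_to_trough_response(nn, prof, 25 + 180), tolerance = 1e-12)
})

test_that("the time-resolved response matches the closed form to numerical precision", {
  nn <- neurons(c(30, -40, 110), c(10, -20, 45), c(35, 20, 50), c(90, 80, 10))
  for (th in c(0, 37, -123, 180)) {
    expect_equal(
      peak_to_trough_response(nn, prof, th, method = "time_resolved"),
      peak_to_trough_response(nn, prof, th, method = "closed_form"),
      tolerance = 1e-9
    )
  }
})

test_that("bilateral mirroring doubles the population and enforces azimuth antisymmetry", {
  pop <- make_afferent_population(313, seed = 1)
  bi <- mirror_bilateral(pop)
  expect_equal(nrow(bi), 626)
  expect_identical(population_laterality(bi), "bilateral")
  expect_equal(sort(wrap_angle(bi$azimuth_deg)),
               sort(wrap_angle(-bi$azimuth_deg)), tolerance = 1e-12)
  # summed horizontal polarization has zero lateral component
  expect_equal(sum(polarization_matrix(bi)[, "y"]), 0, tolerance = 1e-9)
  expect_error(mirror_bilateral(bi), "already bilateral")
  # single neuron at 50 -> pair at +-50
  one <- mirror_bilateral(neurons(50))
  expect_equal(sort(one$azimuth_deg), c(-50, 50))
})

test_that("population-vector decoding is unbiased for uniform populations and exact at 0/180", {
  pu <- make_cosine_population(10000, azimuth_spread_deg = Inf, seed = 7)
  bc <- decode_bias_curve(pu, prof)
  expect_lt(max(abs(bc$bias_deg)), 1)
  bi <- mirror_bilateral(make_afferent_population(313, seed = 3))
  expect_equal(decode_heading(bi, prof, 0), 0, tolerance = 1e-9)
  expect_equal(decode_heading(bi, prof, 180), 180, tolerance = 1e-9)
})

test_that("lateral overrepresentation biases oblique headings laterally", {
  # handcrafted 4-neuron population: tight clusters at +-90
  hp <- mirror_bilateral(neurons(c(85, 95)))
  expect_gt(decode_heading(hp, prof, 45), 45)
  # afferent-like population: positive bias on (0, 50), negative on (130, 180)
  bi <- mirror_bilateral(make_afferent_population(313, seed = 3))
  bc <- decode_bias_curve(bi, prof)
  expect_true(all(bc$bias_deg[bc$stimulus_deg > 0 & bc$stimulus_deg < 50] > 0))
  expect_true(all(bc$bias_deg[bc$stimulus_deg > 130 & bc$stimulus_deg < 180] < 0))
  # mirror property of bilateral populations
  th <- bc$stimulus_deg[bc$stimulus_deg > 0 & bc$stimulus_deg < 180]
  for (t in th) {
    expect_equal(bc$bias_deg[bc$stimulus_deg == t],
                 -bc$bias_deg[bc$stimulus_deg == -t], tolerance = 1e-9)
  }
})

test_that("decoded headings are invariant to sensitivity scale, resting discharge and gravity", {
  bi <- mirror_bilateral(make_afferent_population(50, seed = 9))
  d0 <- decode_heading(bi, prof, 33)
  scaled <- bi
  scaled$sensitivity <- scaled$sensitivity * 7.3
  scaled$resting_discharge <- scaled$resting_discharge + 55
  expect_equal(decode_heading(scaled, prof, 33), d0, tolerance = 1e-9)
  expect_equal(decode_heading(bi, prof, 33, gravity_g = c(0, 0, -3.7)), d0,
               tolerance = 1e-9)
  # decoding requires a bilateral population
  expect_error(decode_heading(make_afferent_population(10, seed = 1), prof, 0),
               "bilateral")
})
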