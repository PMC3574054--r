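test_that("likelihood SD interpolates piecewise-linearly in eccentricity", {
  lik <- likelihood_profile(data.frame(heading_deg = c(0, 90, 180),
                                       sd_deg = c(10, 25, 40)))
  expect_equal(likelihood_sd(lik, 45), 17.5)
  expect_equal(likelihood_sd(lik, -45), likelihood_sd(lik, 45))
  expect_equal(likelihood_sd(lik, 90), 25)
  expect_equal(likelihood_sd(lik, 180), 40)
  expect_error(likelihood_profile(data.frame(heading_deg = 0, sd_deg = -1)),
               "positive")
})

test_that("MAP estimates match a dense brute-force posterior maximization", {
  # constant likelihood SD 20, prior sigma 50, stimulus 45: oracle at 0.01 deg
  lik <- likelihood_profile(data.frame(heading_deg = c(0, 180), sd_deg = c(20, 20)))
  prior <- bimodal_prior(50)
  g <- seq(-179.99, 180, by = 0.01)
  post <- exp(-(g - 45)^2 / (2 * 20^2)) *
    (exp(-(g - 90)^2 / (2 * 50^2)) + exp(-(g + 90)^2 / (2 * 50^2)))
  oracle <- g[which.max(post)]
  expect_gt(oracle, 45) # attracted toward +90
  expect_equal(map_estimate(45, prior, lik), oracle, tolerance = 0.2 / oracle)
  # prior peak coincident with likelihood center
  expect_equal(map_estimate(90, prior, lik), 90)
  # flat-prior limit reproduces the identity
  flat <- bimodal_prior(1e6)
  for (th in c(-150, -45, 0, 60, 180)) {
    expect_equal(map_estimate(th, flat, lik), th, tolerance = 0.11 / max(abs(th), 1))
  }
})

test_that("predicted bias curves are antisymmetric, zero at 0/180, and lateral-attracting", {
  lik <- default_likelihood_profile("vestibular")
  bc <- predict_bias_curve(bimodal_prior(30), lik)
  z <- bc$bias_deg[abs(bc$stimulus_deg) %in% c(0, 180)]
  expect_equal(z, rep(0, length(z)))
  for (t in bc$stimulus_deg[bc$stimulus_deg > 0 & bc$stimulus_deg < 180]) {
    expect_equal(bc$bias_deg[bc$stimulus_deg == t],
                 -bc$bias_deg[bc$stimulus_deg == -t])
  }
  fw <- bc$bias_deg[bc$stimulus_deg > 0 & bc$stimulus_deg < 90]
  expect_true(all(fw >= 0))
  # bias at +-90 is zero (prior peak)
  expect_equal(bc$bias_deg[bc$stimulus_deg == 90], 0)
})

test_that("narrower priors produce larger peak predicted bias", {
  lik <- default_likelihood_profile("vestibular")
  pk <- vapply(c(10, 20, 40, 60, 90, 120), function(sg) {
    max(abs(predict_bias_curve(bimodal_prior(sg), lik,
                               off_cardinal_headings())$bias_deg))
  }, numeric(1))
  expect_true(all(diff(pk) <= 0))
})

test_that("the prior width is recovered by least squares", {
  lik <- default_likelihood_profile("vestibular")
  h <- off_cardinal_headings()
  # noiseless recovery at sigma 30 via scan + refine
  obs <- predict_bias_curve(bimodal_prior(30), lik, h)
  fit <- fit_sigma_prior(obs, lik, search_range = c(10, 60))
  expect_equal(fit$sigma_prior_hat_deg, 30, tolerance = 0.5 / 30)
  expect_gt(fit$r_squared, 0.999)
  expect_false(fit$boundary)
  # noisy recovery at the sigma = 17 scenario (wrapped noise SD 1)
  scan <- sigma_prior_scan(lik, h, sigmas_deg = seq(10, 40, by = 0.5))
  hats <- vapply(1:25, function(i) {
    o <- predict_bias_curve(bimodal_prior(17), lik, h)
    set.seed(900 + i)
    o$bias_deg <- wrap_angle(o$bias_deg + rnorm(nrow(o), 0, 1))
    fit_sigma_prior(o, lik, scan = scan)$sigma_prior_hat_deg
  }, numeric(1))
  expect_equal(mean(hats), 17, tolerance = 2 / 17)
  # observed flat curve: boundary solution at the largest sigma, R^2 = 0 flagged
  flat_obs <- bias_curve(h, rep(0, length(h)))
  ffit <- fit_sigma_prior(flat_obs, lik, scan = scan)
  expect_true(ffit$boundary)
  expect_equal(ffit$sigma_prior_hat_deg, 40)
  expect_equal(ffit$r_squared, 0)
  expect_error(fit_sigma_prior(bias_curve(c(0, 45), c(0, 1)), lik), "at least 8")
})
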