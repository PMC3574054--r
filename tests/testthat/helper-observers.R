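# Shared fixtures, built in code.

# generating bias function used throughout: lateral attraction, 6 deg peaks
gen_bias <- function(theta_deg) 6 * sin(2 * theta_deg * pi / 180)

quiet_observer <- function(noise_sd = 0.01) {
  id_observer(noise_sd_fn = function(th) rep(noise_sd, length(th)),
              lapse_rate = 0)
}

standard_headings <- function() wrap_angle(seq(0, 352.5, by = 7.5))

# headings with the unbiased 0/180 removed, as used for prior fitting
off_cardinal_headings <- function() {
  h <- standard_headings()
  h[!(abs(h) < 1e-9 | abs(abs(h) - 180) < 1e-9)]
}
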