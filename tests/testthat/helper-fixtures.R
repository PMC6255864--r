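# Shared fixture builders. Everything is generated in code at test time.

# square occupancy pulse embedded in a flat trace
make_pulse_trace <- function(pulse_samples, height_nm = 2,
                             pad = 200, sampling_rate = 625e3,
                             noise_sd = 0) {
  h <- c(rep(0, pad), rep(height_nm, pulse_samples), rep(0, pad))
  if (noise_sd > 0) h <- h + rnorm(length(h), 0, noise_sd)
  new_afm_trace(h, sampling_rate)
}

# dwells from a Gaussian mixture truncated at zero, with labels
make_mixture_dwells <- function(n, means_s, sds_s, weights, seed) {
  set.seed(seed)
  lab <- sample(seq_along(means_s), n, replace = TRUE, prob = weights)
  d <- rnorm(n, means_s[lab], sds_s[lab])
  keep <- d > 0
  list(dwell_s = d[keep], label = lab[keep])
}

# clean two-state telegraph (no jitter, no transition ramp)
make_clean_telegraph <- function(duration_s = 6, sampling_rate = 50e3,
                                 mean_dwell_s = 0.03, sigma_nm = 0.17,
                                 seed = 1) {
  cfg <- telegraph_config(mean_dwell_s = mean_dwell_s, transition_s = 0,
                          jitter_nm = c(0, 0),
                          noise = noise_model(sigma_nm), seed = seed)
  simulate_telegraph_trace(cfg, duration_s, sampling_rate)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
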