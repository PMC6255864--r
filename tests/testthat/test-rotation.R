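test_that("the idealizer recovers clean telegraph dwells with small bias", {
  tr <- make_clean_telegraph(duration_s = 8, mean_dwell_s = 0.03,
                             sigma_nm = 0.17, seed = 51)
  gt <- ground_truth(tr)
  id <- idealize_two_state(tr, filter_width = 30)
  gt_dwell <- gt$end_s - gt$start_s
  # >= 95% of dwells of 1 ms or longer are recovered
  n_long_gt <- sum(gt_dwell >= 1e-3)
  n_long_id <- sum(id$dwell_s >= 1e-3)
  expect_gt(n_long_id / n_long_gt, 0.95)
  expect_lt(n_long_id / n_long_gt, 1.05)
  expect_rel_error(mean(id$dwell_s), mean(gt_dwell), 0.10)
  # fitted levels near the configured state heights
  expect_equal(sort(attr(id, "levels_nm")), c(1.72, 2.00),
               tolerance = 0.02)
})

test_that("idealizer dwell bias stays below 10% across signal-to-noise ratios", {
  fw <- 30
  sep <- 0.28
  # bias measured on dwells of at least ten filter widths
  floor_s <- 10 * fw / 50e3
  for (snr in c(3, 5, 10)) {
    sigma <- sep / snr * sqrt(fw)   # per-sample noise giving this SNR
    tr <- make_clean_telegraph(duration_s = 8, mean_dwell_s = 0.03,
                               sigma_nm = sigma, seed = 52 + snr)
    gt_d <- with(ground_truth(tr), end_s - start_s)
    id <- idealize_two_state(tr, filter_width = fw)
    expect_rel_error(mean(id$dwell_s[id$dwell_s >= floor_s]),
                     mean(gt_d[gt_d >= floor_s]), 0.10)
  }
})

test_that("short dwells are retained down to the few-hundred-microsecond range", {
  tr <- make_clean_telegraph(duration_s = 20, mean_dwell_s = 0.026,
                             sigma_nm = 0.10, seed = 53)
  id <- idealize_two_state(tr, filter_width = 30)
  expect_gt(nrow(id), 300)
  expect_lt(min(id$dwell_s), 1.5e-3)
  expect_gt(min(id$dwell_s), 0)
})

test_that("symmetric telegraphs show no state preference", {
  tr <- make_clean_telegraph(duration_s = 20, mean_dwell_s = 0.03,
                             sigma_nm = 0.17, seed = 54)
  id <- idealize_two_state(tr, filter_width = 30)
  t_high <- sum(id$dwell_s[id$state == "high"])
  f_high <- t_high / sum(id$dwell_s)
  n <- nrow(id)
  expect_lt(abs(f_high - 0.5), 3 * 0.5 / sqrt(n) + 0.05)
})

test_that("dwell statistics report mean, s.e.m. and survival correctly", {
  set.seed(55)
  dw <- tibble::tibble(state = rep(c("low", "high"), length.out = 2053),
                       dwell_s = rexp(2053, 1 / 0.035))
  ds <- dwell_statistics(dw)
  pooled <- ds$per_state[ds$per_state$state == "pooled", ]
  expect_equal(pooled$n, 2053)
  expect_lt(abs(pooled$mean_s - 0.035), 3 * pooled$sem_s)
  # survival function is a proper decreasing step curve
  expect_true(all(diff(ds$survival$survival) <= 0))
  expect_equal(max(ds$survival$survival), 1 - 1 / 2053)
  expect_error(dwell_statistics(dw[1, ]), class = "heightspec_data_error")
})

test_that("a mixture of exponential dwells bends the log-survival curve", {
  set.seed(56)
  n <- 3000
  comp <- sample(1:3, n, TRUE)
  mix <- rexp(n, 1 / c(0.013, 0.041, 0.096)[comp])
  pure <- rexp(n, 1 / mean(mix))
  curvature <- function(d) {
    s <- dwell_statistics(tibble::tibble(state = "x", dwell_s = d))$survival
    keep <- s$survival > 0.01
    max(abs(resid(lm(log(s$survival[keep]) ~ s$t_s[keep]))))
  }
  expect_gt(curvature(mix), 2 * curvature(pure))
})

test_that("rotation energetics follow the dwell-ratio relation", {
  en <- rotation_energetics(0.035, 0.018)
  expect_equal(en$delta_g_kbt, -log(18 / 35), tolerance = 1e-12)
  expect_equal(en$angular_velocity_deg_s, 60 / 0.018, tolerance = 1e-9)
  expect_equal(en$rpm, 60 / 0.018 / 6, tolerance = 1e-9)
  # the HS-mode state dwell (26 ms) gives a smaller barrier
  expect_equal(rotation_energetics(0.026, 0.018)$delta_g_kbt, 0.368,
               tolerance = 1e-3)
  # symmetric case and antisymmetry under exchanging the two times
  expect_equal(rotation_energetics(0.02, 0.02)$delta_g_kbt, 0)
  expect_equal(rotation_energetics(0.04, 0.01)$delta_g_kbt,
               -rotation_energetics(0.01, 0.04)$delta_g_kbt)
  expect_error(rotation_energetics(0, 0.01),
               class = "heightspec_config_error")
})

test_that("position traces from a kymograph anti-correlate and idealize", {
  sch <- rotation_schedule(rep(0.08, 10),
                           direction = rep(c(1, -1), length.out = 9))
  ky <- simulate_rotation_kymograph(sch, noise = noise_model(0.08),
                                    seed = 57)
  st <- extract_position_traces(ky)
  expect_lt(st$correlation, 0)
  # the idealized difference trace reproduces the schedule's plateaus
  expect_equal(nrow(st$idealization), 10)
  # plateau separation in the difference trace is about twice the lobe
  # height contrast
  expect_gt(diff(attr(st$idealization, "levels_nm")), 1)
})

test_that("difference traces cancel common-mode errors", {
  sch <- rotation_schedule(rep(0.08, 8),
                           direction = rep(c(1, -1), length.out = 7))
  ky <- simulate_rotation_kymograph(sch, noise = noise_model(0.05),
                                    seed = 58)
  # inject a common-mode baseline wobble into every row
  wobble <- 0.25 * sin(seq_len(ncol(ky)) / 8)
  kyw <- ky + matrix(wobble, nrow(ky), ncol(ky), byrow = TRUE)
  attributes(kyw) <- attributes(ky)
  st <- extract_position_traces(kyw)
  # within-plateau spread: the difference trace beats both raw traces
  id <- st$idealization
  longest <- which.max(id$dwell_s)
  lp <- attr(ky, "line_period_s")
  # trim half a transition (the idealized dwell spans mid-ramp to mid-ramp)
  rows <- which((st$traces$time_s >= id$start_s[longest] + 5 * lp) &
                (st$traces$time_s <= id$end_s[longest] - 5 * lp))
  expect_lt(sd(st$traces$diff_nm[rows]),
            max(sd(st$traces$h0_nm[rows]), sd(st$traces$h60_nm[rows])))
})

test_that("a static object yields no two-state structure", {
  sch <- rotation_schedule(0.3)
  ky <- simulate_rotation_kymograph(sch, noise = noise_model(0.05),
                                    seed = 59)
  expect_error(extract_position_traces(ky),
               class = "heightspec_not_two_state")
  expect_error(measure_rotation_transitions(ky),
               class = "heightspec_not_two_state")
  expect_error(extract_position_traces(ky, x0_nm = -100, x60_nm = 0),
               class = "heightspec_config_error")
})

test_that("transition directions match the schedule for all resolvable rotations", {
  dirs <- c(1, -1, 1, 1, -1, -1, 1, -1)
  sch <- rotation_schedule(rep(0.1, 9), direction = dirs)
  for (noise_sd in c(1e-9, 0.1)) {
    ky <- simulate_rotation_kymograph(sch, noise = noise_model(noise_sd),
                                      seed = 60)
    trn <- measure_rotation_transitions(ky)
    expect_equal(nrow(trn), length(dirs))
    expect_equal(trn$direction, as.integer(dirs))
    # 18 ms at 2.4 ms per line, +-1 line quantization and +-1 line of
    # noise-induced plateau ambiguity
    expect_true(all(trn$n_lines %in% 5:10))
  }
})

test_that("unresolvable and edge transitions are flagged or discarded", {
  sch <- rotation_schedule(rep(0.1, 4), direction = c(1, -1, 1),
                           transition_s = 0)
  ky <- simulate_rotation_kymograph(sch, noise = noise_model(1e-9),
                                    seed = 61)
  trn <- measure_rotation_transitions(ky)
  expect_true(all(trn$n_lines <= 1))
  expect_true(all(!trn$resolvable))
})
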