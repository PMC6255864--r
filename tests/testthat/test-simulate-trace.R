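test_that("a protein-free trace is Gaussian baseline noise at the configured RMS", {
  cfg <- sim_config(density_um2 = 0, duration_s = 1, seed = 1)
  tr <- simulate_diffusion_trace(cfg)
  expect_equal(nrow(tr), 625000)
  expect_lt(abs(sd(tr$height_nm) - 0.17) / 0.17, 0.02)
  expect_lt(abs(mean(tr$height_nm)), 0.005)
  expect_equal(nrow(ground_truth(tr)), 0)
})

test_that("noise-only samples exceed 5 sigma at the one-sided Gaussian tail rate", {
  set.seed(2)
  n <- 1e7
  x <- rnorm(n, 0, 0.17)
  count <- sum(x > 5 * 0.17)
  expected <- n * pnorm(-5)          # ~2.87 counts
  # within 3 Poisson standard deviations
  expect_lte(abs(count - expected), 3 * sqrt(expected) + 1)
})

test_that("an immobile particle under the tip produces a 2 nm plateau", {
  cfg <- sim_config(density_um2 = 1, d_um2s = 0, duration_s = 0.01,
                    box_side_um = 0.5, seed = 3)
  tr <- simulate_diffusion_trace(
    cfg, init_positions = list(matrix(c(0.25, 0.25), 1)))
  late <- tr$height_nm[2000:6250]    # past the feedback settling time
  expect_equal(mean(late), 2, tolerance = 0.02)
  gt <- ground_truth(tr)
  expect_equal(nrow(gt), 1)
  expect_equal(gt$start_idx, 1)
  expect_equal(gt$end_idx, nrow(tr))
})

test_that("ground-truth occupancy equals the frame-by-frame distance oracle", {
  g <- species_geometry()
  cfg <- sim_config(density_um2 = 100, d_um2s = 0.8, duration_s = 2,
                    box_side_um = 0.3, seed = 4)
  tr <- simulate_diffusion_trace(cfg, store_trajectories = TRUE)
  traj <- unlist(attr(tr, "trajectories"), recursive = FALSE)
  orc <- occupancy_oracle(traj, c(0.15, 0.15), g$w_nm, 0.3, 625e3)
  expect_equal(attr(orc, "occupied_fraction"),
               attr(tr, "occupied_fraction"), tolerance = 1e-9)
  gt <- ground_truth(tr)
  expect_equal(orc$start_idx, gt$start_idx)
  expect_equal(orc$end_idx, gt$end_idx)
})

test_that("occupancy oracle handles degenerate trajectories", {
  expect_equal(nrow(occupancy_oracle(list(), c(0, 0), 10, 1, 625e3)), 0)
  # particle parked inside the detection disk the whole run
  tr1 <- matrix(rep(c(0.5, 0.5), each = 100), ncol = 2)
  o1 <- occupancy_oracle(tr1, c(0.5, 0.5), 10.3, 1, 625e3)
  expect_equal(nrow(o1), 1)
  expect_equal(o1$end_idx - o1$start_idx + 1, 100)
  # crafted path crossing the disk once for exactly 30 samples
  xs <- seq(0.4, 0.6, length.out = 100)
  w_um <- 10.3e-3
  inside <- abs(xs - 0.5) < w_um / 2
  expect_equal(sum(inside), sum(rle(inside)$lengths[rle(inside)$values]))
  o2 <- occupancy_oracle(cbind(xs, 0.5), c(0.5, 0.5), 10.3, 1, 625e3)
  expect_equal(nrow(o2), 1)
  expect_equal(o2$end_idx - o2$start_idx + 1, sum(inside))
  # mismatched lengths error
  expect_error(
    occupancy_oracle(list(tr1, tr1[1:10, ]), c(0, 0), 10, 1, 625e3),
    class = "heightspec_config_error")
})

test_that("a fixed seed reproduces the trace bit for bit", {
  cfg <- sim_config(density_um2 = 50, duration_s = 0.2,
                    box_side_um = 0.3, seed = 5)
  tr1 <- simulate_diffusion_trace(cfg)
  tr2 <- simulate_diffusion_trace(cfg)
  expect_identical(tr1$height_nm, tr2$height_nm)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(duration_s = 0), class = "heightspec_config_error")
  expect_error(sim_config(sampling_rate = -1),
               class = "heightspec_config_error")
  expect_error(sim_config(box_side_um = 0), class = "heightspec_config_error")
  expect_error(sim_config(box_side_um = 0.05),
               class = "heightspec_config_error")  # < 10 detection widths
  expect_error(sim_config(density_um2 = -1),
               class = "heightspec_config_error")
})

test_that("detected events match oracle occupancy on noiseless traces", {
  # near-zero noise so detection reflects the signal alone
  cfg <- sim_config(density_um2 = 100, d_um2s = 0.8, duration_s = 2,
                    box_side_um = 0.3, noise = noise_model(1e-9), seed = 6)
  tr <- simulate_diffusion_trace(cfg)
  gt <- ground_truth(tr)
  gt_long <- gt[gt$end_idx - gt$start_idx + 1 >= 13, ]   # >= ~20 us

  # (a) detection on the ideal occupancy signal: boundaries exact
  ideal <- numeric(nrow(tr))
  for (i in seq_len(nrow(gt))) ideal[gt$start_idx[i]:gt$end_idx[i]] <- 2
  ev_ideal <- detect_events(new_afm_trace(ideal, 625e3), 0.85)
  expect_equal(nrow(ev_ideal), nrow(gt))
  expect_equal(ev_ideal$start_idx, gt$start_idx)
  expect_equal(ev_ideal$end_idx, gt$end_idx)

  # (b) with the feedback surrogate in line: a Brownian particle skitters
  # across the detection boundary, so the filter bridges rapid re-entries
  # and one event covers a cluster of oracle intervals. Every resolved
  # oracle interval must be covered by a detected event up to the filter
  # rise/decay (a few samples at tau_fb = 6 us).
  ev <- detect_events(tr, 0.85)
  for (i in seq_len(nrow(gt_long))) {
    covered <- any(ev$start_idx <= gt_long$start_idx[i] + 8 &
                   ev$end_idx >= gt_long$end_idx[i] - 8)
    expect_true(covered)
  }
  # occupancy fraction from detection close to the oracle fraction
  f_det <- sum(ev$dwell_s) / attr(ev, "t_total_s")
  expect_equal(f_det, attr(tr, "occupied_fraction"), tolerance = 0.05)
})
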