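test_that("dissociation constants are recovered from binding isotherms", {
  # noiseless: exact recovery, and fraction = 1/2 at [A] = Kd
  d <- tibble::tibble(a_um2 = c(220 / 3, 220, 3 * 220))
  d$fraction <- d$a_um2 / (d$a_um2 + 220)
  expect_equal(d$fraction[2], 0.5)
  f <- fit_kd_curve(d)
  expect_equal(f$kd_um2, 220, tolerance = 1e-9)

  # 5% multiplicative noise, 8 points spanning 0.1-10x Kd, 100 replicates
  set.seed(41)
  kds <- replicate(100, {
    a <- 220 * 10^seq(-1, 1, length.out = 8)
    fr <- pmin(a / (a + 220) * (1 + rnorm(8, 0, 0.05)), 1)
    fit_kd_curve(tibble::tibble(a_um2 = a, fraction = fr))$kd_um2
  })
  expect_lt(abs(median(kds) - 220) / 220, 0.10)
})

test_that("unidentifiable or malformed isotherms are rejected", {
  expect_error(fit_kd_curve(tibble::tibble(a_um2 = c(1, 2),
                                           fraction = c(0.1, 0.2))),
               class = "heightspec_data_error")
  expect_error(fit_kd_curve(tibble::tibble(a_um2 = c(1, 2, 3),
                                           fraction = c(0, 1, 1))),
               class = "heightspec_data_error")
  expect_error(fit_kd_curve(tibble::tibble(a_um2 = c(1, 2, 3),
                                           fraction = c(0.1, 0.5, 1.2))),
               class = "heightspec_data_error")
})

test_that("the two-species equilibrium matches the closed-form quadratic", {
  for (ct in c(1, 50, 1000)) {
    for (kd in c(30, 220, 900)) {
      eq <- equilibrium_distribution(ct, kd_um2 = kd, n_max = 2)
      a_closed <- (-kd + sqrt(kd^2 + 8 * kd * ct)) / 4
      expect_equal(eq$density_um2[eq$n == 1], a_closed,
                   tolerance = 1e-12)
      expect_equal(eq$density_um2[eq$n == 2], a_closed^2 / kd,
                   tolerance = 1e-10)
    }
  }
})

test_that("mass is conserved across random equilibrium configurations", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    ct <- 10^runif(1, -1, 4)
    kd <- 10^runif(4, 1, 3)
    eq <- equilibrium_distribution(ct, kd_um2 = kd, n_max = 10)
    err <- abs(sum(eq$n * eq$density_um2) - ct) / ct
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-9)
})

test_that("oligomer populations rise and fall in sequence with concentration", {
  grid <- exp(seq(log(1), log(1e4), length.out = 400))
  eq <- equilibrium_distribution(grid)
  f <- function(n) eq$mass_fraction[eq$n == n]
  # monomer fraction strictly decreasing
  expect_true(all(diff(f(1)) < 0))
  # f2..f4 unimodal with strictly increasing argmax positions
  argmax <- vapply(2:4, function(n) grid[which.max(f(n))], 0)
  expect_true(all(diff(argmax) > 0))
  for (n in 2:4) {
    v <- f(n)
    pk <- which.max(v)
    expect_true(all(diff(v[seq_len(pk)]) > 0))
    expect_true(all(diff(v[pk:length(v)]) < 0))
  }
  # dilute limit: monomers only
  dil <- equilibrium_distribution(1e-6)
  expect_equal(dil$mass_fraction[dil$n == 1], 1, tolerance = 1e-3)
})

test_that("the dimer population peaks near its dissociation constant", {
  grid <- exp(seq(log(1), log(1e4), length.out = 2000))
  eq <- equilibrium_distribution(grid)
  f2 <- eq$mass_fraction[eq$n == 2]
  peak_c <- grid[which.max(f2)]
  expect_gt(peak_c, 220 / 2)
  expect_lt(peak_c, 220 * 2)
})

test_that("free energies follow the log-ratio of populations", {
  expect_equal(oligomer_free_energy(5, 5), 0)
  expect_equal(oligomer_free_energy(exp(1) * 3, 3), 1, tolerance = 1e-12)
  expect_error(oligomer_free_energy(0, 1),
               class = "heightspec_config_error")
  # self-consistency with the equilibrium state at 500 um^-2
  eq <- equilibrium_distribution(500)
  c1 <- eq$density_um2[eq$n == 1]
  c2 <- eq$density_um2[eq$n == 2]
  expect_equal(oligomer_free_energy(c1, c2), log(c1 / c2))
})

test_that("partition coefficients convert to binding free energies", {
  # P = 1 -> dG0 = 0: bulk density equal to the slab-volumetric surface density
  c_surf <- 1.0
  bulk_matching <- (c_surf / 2e-3) / 6.02214076e8
  expect_equal(membrane_binding_free_energy(c_surf, bulk_matching)$delta_g0_kbt,
               0, tolerance = 1e-9)
  # P = 1/e -> dG0 = -1 kBT
  expect_equal(
    membrane_binding_free_energy(c_surf, bulk_matching / exp(1))$delta_g0_kbt,
    -1, tolerance = 1e-9)
  # 127 nM bulk over 1 um^-2 surface in a 2 nm slab: about -1.9 kBT
  g <- membrane_binding_free_energy(1.0, 127e-9, h_nm = 2)
  expect_equal(g$delta_g0_kbt, -1.878, tolerance = 1e-3)
  expect_error(membrane_binding_free_energy(1, 1e-7, h_nm = 0),
               class = "heightspec_config_error")
})

test_that("the logarithmic size dependence of membrane diffusion is fitted", {
  # exact generation -> exact recovery
  r <- c(4, 6, 9, 12)
  d <- 0.31 * log(40 / r)
  f <- fit_saffman_delbruck(tibble::tibble(r_nm = r, d_um2s = d))
  expect_equal(f$a, 0.31, tolerance = 1e-6)
  expect_equal(f$b_nm, 40, tolerance = 1e-4)

  # measured oligomer series: radii scale as sqrt(n)
  ser <- tibble::tibble(r_nm = 4.15 * sqrt(1:5),
                        d_um2s = c(0.8, 0.63, 0.58, 0.50, 0.46))
  fs <- fit_saffman_delbruck(ser)
  gl <- glance(fs)
  expect_lt(gl$rms, 0.05)
  expect_true(gl$strictly_decreasing)
  expect_true(gl$b_gt_rmax)

  expect_error(fit_saffman_delbruck(tibble::tibble(r_nm = c(1, 2),
                                                   d_um2s = c(1, 0.5))),
               class = "heightspec_data_error")
  expect_warning(fit_saffman_delbruck(
    tibble::tibble(r_nm = c(1, 2, 3), d_um2s = c(0.5, 0.9, 0.4))),
    "increases")
})

test_that("the critical calcium concentration is solved from the exponential fit", {
  # exact data -> exact parameters
  ca <- c(40, 80, 120, 160)
  cs <- 0.2 * exp(0.04 * ca)
  f <- fit_critical_calcium(tibble::tibble(ca_um = ca, c_um2 = cs), 500)
  expect_equal(f$a, 0.2, tolerance = 1e-9)
  expect_equal(f$k_per_um, 0.04, tolerance = 1e-9)
  expect_equal(f$ca_critical_um, log(500 / 0.2) / 0.04, tolerance = 1e-6)

  # the two printed anchor conditions give ~215 uM at 500 um^-2
  two <- fit_critical_calcium(tibble::tibble(ca_um = c(50, 200),
                                             c_um2 = c(1.0, 285)), 500)
  expect_equal(two$ca_critical_um, 214.9, tolerance = 0.01)

  # noisy replicates: median crossing within 10%
  set.seed(43)
  truth <- log(500 / 0.2) / 0.04
  est <- replicate(100, {
    cas <- seq(40, 240, length.out = 6)
    cc <- 0.2 * exp(0.04 * cas) * (1 + rnorm(6, 0, 0.10))
    fit_critical_calcium(tibble::tibble(ca_um = cas, c_um2 = abs(cc)),
                         500)$ca_critical_um
  })
  expect_lt(abs(median(est) - truth) / truth, 0.10)

  expect_error(fit_critical_calcium(tibble::tibble(ca_um = 50, c_um2 = 1)),
               class = "heightspec_data_error")
  expect_error(fit_critical_calcium(tibble::tibble(ca_um = c(50, 100),
                                                   c_um2 = c(-1, 5))),
               class = "heightspec_config_error")
})

test_that("the measured Kd matrix has the expected structure", {
  kd <- a5_kd_matrix()
  expect_equal(dim(kd), c(4, 4))
  expect_true(all(kd > 0))
  expect_false(isSymmetric(unclass(kd)))
  rr <- attr(kd, "reduced_reliability")
  expect_true(rr["tetramer", "tetramer"])
  expect_false(rr["monomer", "tetramer"])
})
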