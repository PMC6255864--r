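#' Fit a 2D dissociation constant from binding-fraction data
#'
#' For surface species associating in two dimensions,
#' `[AB] = [A][B]/Kd`, so the fraction of B found in complex follows a
#' binding isotherm in the partner density:
#' `fraction = [A] / ([A] + Kd)`. This fits that isotherm by nonlinear
#' least squares and reports the Kd with a 95% confidence interval from
#' the fit covariance.
#'
#' @param data Data frame with columns `a_um2` (partner surface density,
#'   um^-2) and `fraction` (fraction of B in complex, in \[0, 1\]).
#' @return A `kd_fit` object with [tidy()]/[glance()] methods;
#'   `tidy()` gives `kd_um2`, `std_error`, `conf_low`, `conf_high`.
#' @examples
#' d <- tibble::tibble(a_um2 = c(73, 220, 660),
#'                     fraction = a_um2 / (a_um2 + 220))
#' tidy(fit_kd_curve(d))  # recovers Kd = 220 exactly
#' @export
fit_kd_curve <- function(data) {
  if (nrow(data) < 3) {
    rlang::abort("Need at least 3 concentration points.",
                 class = "heightspec_data_error")
  }
  if (any(data$fraction < 0 | data$fraction > 1)) {
    rlang::abort("Fractions must lie in [0, 1].",
                 class = "heightspec_data_error")
  }
  if (all(data$fraction %in% c(0, 1))) {
    rlang::abort("All fractions are 0 or 1: Kd is unidentifiable.",
                 class = "heightspec_data_error")
  }
  fit <- minpack.lm::nlsLM(fraction ~ a_um2 / (a_um2 + kd), data = data,
                           start = list(kd = stats::median(data$a_um2)),
                           lower = 1e-12, upper = Inf)
  kd <- stats::coef(fit)[["kd"]]
  se <- sqrt(stats::vcov(fit)[1, 1])
  structure(list(kd_um2 = kd, std_error = se,
                 conf_low = kd - 1.96 * se, conf_high = kd + 1.96 * se,
                 fit = fit, data = data),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd = %.4g um^-2 (95%% CI %.4g-%.4g)\n",
              x$kd_um2, x$conf_low, x$conf_high))
  invisible(x)
}

#' @export
tidy.kd_fit <- function(x, ...) {
  tibble::tibble(term = "kd_um2", estimate = x$kd_um2,
                 std_error = x$std_error,
                 conf_low = x$conf_low, conf_high = x$conf_high)
}

#' @export
glance.kd_fit <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble::tibble(kd_um2 = x$kd_um2, sigma = sqrt(mean(r^2)),
                 n = nrow(x$data))
}

#' Measured 2D dissociation constants for annexin-V oligomerization
#'
#' The 4x4 matrix of 2D dissociation constants (um^-2) for association of
#' an i-mer (rows) with a j-mer (columns) of membrane-bound annexin-V
#' trimers, as measured on supported lipid bilayers. Entries whose
#' product exceeds 5 units have reduced reliability because all
#' aggregates above n = 4 are pooled during fitting; these are flagged by
#' `attr(, "reduced_reliability")`.
#'
#' @return A 4x4 numeric matrix with dimnames monomer..tetramer and
#'   attribute `reduced_reliability` (logical matrix).
#' @export
a5_kd_matrix <- function() {
  m <- matrix(c(220, 170, 650, 200,
                152, 444, 210, 128,
                260, 210, 180, 109,
                170, 106,  91,  52),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("monomer", "dimer", "trimer", "tetramer"),
                              c("monomer", "dimer", "trimer", "tetramer")))
  rr <- outer(1:4, 1:4, `+`) > 5
  dimnames(rr) <- dimnames(m)
  attr(m, "reduced_reliability") <- rr
  m
}

#' Equilibrium oligomer distribution by stepwise monomer addition
#'
#' Solves the mass-conserving equilibrium distribution of oligomers built
#' by stepwise addition of single trimers:
#' `[A_n] = [A_1] [A_(n-1)] / Kd_n`, where `Kd_n` is the dissociation
#' constant of the n-mer-forming step (the monomer row of the Kd matrix).
#' The free monomer density is found by monotone root-finding on the
#' conservation constraint `sum(n [A_n]) = c_total`. Steps beyond the
#' supplied Kd values reuse the last one.
#'
#' @param c_total Total surface concentration(s) in trimer units, um^-2.
#' @param kd_um2 Stepwise dissociation constants, um^-2: the first entry
#'   governs dimer formation, the second trimer formation, and so on.
#'   Default is the monomer row of [a5_kd_matrix()].
#' @param n_max Largest explicit oligomer size.
#' @param pool_from Oligomer sizes at or above this are pooled into class
#'   `"o"` in the `class` column (mirroring the experimental analysis).
#' @return Tibble, one row per (`c_total`, `n`): `density_um2` (number
#'   density of the n-mer), `mass_fraction` (`n [A_n] / c_total`), and
#'   `class` ("1".."4", "o").
#' @export
equilibrium_distribution <- function(c_total,
                                     kd_um2 = a5_kd_matrix()["monomer", ],
                                     n_max = 10, pool_from = 5) {
  stopifnot_nonneg(c_total, "c_total")
  stopifnot_positive(kd_um2, "kd_um2")
  kd_steps <- rep_len(c(kd_um2, rep(kd_um2[length(kd_um2)], n_max)),
                      n_max - 1)
  dens_of <- function(a) {
    cn <- numeric(n_max)
    cn[1] <- a
    for (n in seq_len(n_max - 1)) cn[n + 1] <- cn[n] * a / kd_steps[n]
    cn
  }
  one <- function(ct) {
    if (ct == 0) {
      cn <- numeric(n_max)
    } else {
      g <- function(a) sum(seq_len(n_max) * dens_of(a)) - ct
      a <- stats::uniroot(g, c(0, ct), tol = max(1e-14, ct * 1e-13))$root
      cn <- dens_of(a)
      # polish: rescale residual mass error onto the monomer via one
      # Newton step to keep conservation tight
      a <- a - g(a) / sum(seq_len(n_max)^2 * dens_of(a) / max(a, 1e-300))
      if (is.finite(a) && a > 0) cn <- dens_of(a)
    }
    tibble::tibble(c_total = ct, n = seq_len(n_max), density_um2 = cn,
                   mass_fraction = if (ct > 0) seq_len(n_max) * cn / ct
                                   else c(1, numeric(n_max - 1)))
  }
  out <- dplyr::bind_rows(lapply(c_total, one))
  out$class <- ifelse(out$n >= pool_from, "o", as.character(out$n))
  out
}

#' Free-energy difference between oligomer states
#'
#' `Delta G = ln(c_n / c_m)` in units of kBT, from the equilibrium
#' surface concentrations of two oligomer species.
#'
#' @param c_n,c_m Surface concentrations, um^-2 (both > 0).
#' @return Free-energy difference(s), kBT.
#' @export
oligomer_free_energy <- function(c_n, c_m) {
  stopifnot_positive(c_n, "c_n")
  stopifnot_positive(c_m, "c_m")
  log(c_n / c_m)
}

#' Membrane-binding free energy from a partition coefficient
#'
#' The partition coefficient `P = [c_solution] / [c_surface]` compares the
#' bulk number density with the surface population expressed as a
#' volumetric density in a slab of thickness `h` (default 2 nm, the height
#' of membrane-bound annexin-V); the standard binding free energy is then
#' `Delta G0 = ln(P)` in kBT (negative for favourable binding).
#'
#' @param c_surface_um2 Surface concentration, um^-2.
#' @param c_bulk_molar Bulk concentration, mol/L.
#' @param h_nm Slab thickness used for the surface-to-volume conversion,
#'   nm.
#' @return One-row tibble: `partition_coefficient`, `delta_g0_kbt`,
#'   `h_nm`.
#' @examples
#' membrane_binding_free_energy(1.0, 127e-9)  # ~ -1.9 kBT
#' @export
membrane_binding_free_energy <- function(c_surface_um2, c_bulk_molar,
                                         h_nm = 2.0) {
  stopifnot_positive(c_surface_um2, "c_surface_um2")
  stopifnot_positive(c_bulk_molar, "c_bulk_molar")
  stopifnot_positive(h_nm, "h_nm")
  bulk_um3 <- molar_to_per_um3(c_bulk_molar)
  surf_um3 <- c_surface_um2 / nm_to_um(h_nm)
  p <- bulk_um3 / surf_um3
  tibble::tibble(partition_coefficient = p, delta_g0_kbt = log(p),
                 h_nm = h_nm)
}

#' Fit the Saffman-Delbruck size dependence of membrane diffusion
#'
#' Membrane-embedded and membrane-bound particles diffuse with only a
#' weak (logarithmic) dependence on their radius, `D = a ln(b / r)`.
#' Fits that form to (radius, D) pairs.
#'
#' @param data Data frame with columns `r_nm` (particle radius, nm) and
#'   `d_um2s` (diffusion coefficient, um^2 s^-1).
#' @return An `sd_fit` object with `tidy()`/`glance()`; `glance()`
#'   reports the residual RMS and whether the fitted curve is strictly
#'   decreasing over the data range.
#' @export
fit_saffman_delbruck <- function(data) {
  if (nrow(data) < 3) {
    rlang::abort("Need at least 3 (radius, D) pairs.",
                 class = "heightspec_data_error")
  }
  if (any(diff(data$d_um2s[order(data$r_nm)]) > 0)) {
    rlang::warn("D increases with radius somewhere: fit returned anyway.")
  }
  lin <- stats::lm(d_um2s ~ log(r_nm), data = data)
  a0 <- -stats::coef(lin)[[2]]
  b0 <- exp(stats::coef(lin)[[1]] / max(a0, 1e-9))
  fit <- minpack.lm::nlsLM(d_um2s ~ a * log(b / r_nm), data = data,
                           start = list(a = max(a0, 1e-3),
                                        b = max(b0, max(data$r_nm) * 2)))
  co <- stats::coef(fit)
  pred <- function(r) co[["a"]] * log(co[["b"]] / r)
  structure(list(a = co[["a"]], b_nm = co[["b"]], fit = fit, data = data,
                 predict = pred,
                 rms = sqrt(mean(stats::resid(fit)^2))),
            class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("<sd_fit> D = %.4g * ln(%.4g / r), residual RMS %.3g\n",
              x$a, x$b_nm, x$rms))
  invisible(x)
}

#' @export
tidy.sd_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b_nm"), estimate = c(x$a, x$b_nm))
}

#' @export
glance.sd_fit <- function(x, ...) {
  rr <- range(x$data$r_nm)
  grid <- seq(rr[1], rr[2], length.out = 200)
  tibble::tibble(rms = x$rms, b_gt_rmax = x$b_nm > rr[2],
                 strictly_decreasing = all(diff(x$predict(grid)) < 0),
                 n = nrow(x$data))
}

#' Critical calcium concentration from an exponential binding curve
#'
#' Surface concentration grows exponentially with the bulk calcium
#' concentration, `c = A exp(k Ca)`. Fits that model (log-linear least
#' squares) and solves for the calcium concentration at which a critical
#' surface concentration is reached.
#'
#' @param data Data frame with `ca_um` (bulk calcium, uM) and `c_um2`
#'   (surface concentration, um^-2; all > 0).
#' @param c_critical_um2 Critical surface concentration, um^-2.
#' @return One-row tibble: `a`, `k_per_um`, `ca_critical_um`.
#' @export
fit_critical_calcium <- function(data, c_critical_um2 = 500) {
  if (nrow(data) < 2) {
    rlang::abort("Need at least 2 points.", class = "heightspec_data_error")
  }
  stopifnot_positive(data$c_um2, "c_um2")
  stopifnot_positive(c_critical_um2, "c_critical_um2")
  fit <- stats::lm(log(c_um2) ~ ca_um, data = data)
  k <- stats::coef(fit)[[2]]
  a <- exp(stats::coef(fit)[[1]])
  tibble::tibble(a = a, k_per_um = k,
                 ca_critical_um = (log(c_critical_um2) - log(a)) / k)
}
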