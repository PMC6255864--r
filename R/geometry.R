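#' Geometry of a diffusing membrane-bound species under the AFM tip
#'
#' Describes the footprint of an annexin-V trimer (A5) oligomer, the tip
#' radius, and the resulting effective detection width. A particle is
#' detected whenever its centre is within `w/2` of the tip position, with
#' `w = d_p + 2 * r_tip`: the molecule's footprint diameter broadened by
#' the tip radius on either side. Oligomer area grows linearly with the
#' number of trimers, so the footprint diameter scales as
#' `d_p(n) = d_p(1) * sqrt(n)`.
#'
#' The default trimer footprint of 8.3 nm with a 1 nm tip radius gives a
#' detection width of 10.3 nm, for which a 33 us dwell corresponds to a
#' diffusion coefficient of 0.8 um^2 s^-1.
#'
#' @param n_units Number of A5 trimers in the oligomer (>= 1).
#' @param d_p_nm Footprint diameter of a single trimer, nm.
#' @param tip_radius_nm AFM tip radius, nm.
#' @return A one-row tibble with columns `n_units`, `d_p_nm`,
#'   `tip_radius_nm` and `w_nm` (effective detection width).
#' @examples
#' species_geometry()                      # single A5 trimer, w = 10.3 nm
#' species_geometry(n_units = 4)          # tetramer, d_p doubles
#' @export
species_geometry <- function(n_units = 1, d_p_nm = 8.3, tip_radius_nm = 1.0) {
  if (!is.numeric(n_units) || n_units < 1 || n_units != round(n_units)) {
    rlang::abort("`n_units` must be a positive integer.",
                 class = "heightspec_config_error")
  }
  stopifnot_positive(d_p_nm, "d_p_nm")
  stopifnot_nonneg(tip_radius_nm, "tip_radius_nm")
  d <- d_p_nm * sqrt(n_units)
  tibble::tibble(
    n_units = as.integer(n_units),
    d_p_nm = d,
    tip_radius_nm = tip_radius_nm,
    w_nm = d + 2 * tip_radius_nm
  )
}

#' Effective detection width from a dwell-time / diffusion calibration pair
#'
#' For two-dimensional Brownian motion through a detection disk of width
#' `w`, the characteristic dwell time is `tau_D = w^2 / (4 D)`. Given one
#' known (tau_D, D) pair this inverts to the width that produced it.
#'
#' @param tau_s Dwell time, seconds.
#' @param d_um2s Diffusion coefficient, um^2 s^-1.
#' @return Detection width in nm.
#' @examples
#' # a single protomer diffusing at 1 um^2/s dwells 2.7 us:
#' detection_width_from_dwell(2.7e-6, 1)
#' @export
detection_width_from_dwell <- function(tau_s, d_um2s) {
  stopifnot_positive(tau_s, "tau_s")
  stopifnot_positive(d_um2s, "d_um2s")
  um_to_nm(sqrt(4 * d_um2s * tau_s))
}

#' Convert between dwell time and diffusion coefficient
#'
#' `tau_D = w^2 / (4 D)` for a molecule of effective detection width `w`
#' crossing the fixed tip position by 2D Brownian motion.
#' `dwell_to_diffusion()` and `diffusion_to_dwell()` are exact inverses.
#'
#' @param tau_s Dwell time(s), seconds.
#' @param d_um2s Diffusion coefficient(s), um^2 s^-1.
#' @param w_nm Effective detection width, nm.
#' @return Diffusion coefficient in um^2 s^-1, or dwell time in seconds.
#' @examples
#' dwell_to_diffusion(33e-6, w_nm = 10.3)   # ~0.80 um^2/s
#' diffusion_to_dwell(0.8, w_nm = 10.3)     # ~33 us
#' @export
dwell_to_diffusion <- function(tau_s, w_nm) {
  stopifnot_positive(tau_s, "tau_s")
  stopifnot_positive(w_nm, "w_nm")
  nm_to_um(w_nm)^2 / (4 * tau_s)
}

#' @rdname dwell_to_diffusion
#' @export
diffusion_to_dwell <- function(d_um2s, w_nm) {
  stopifnot_positive(d_um2s, "d_um2s")
  stopifnot_positive(w_nm, "w_nm")
  nm_to_um(w_nm)^2 / (4 * d_um2s)
}
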