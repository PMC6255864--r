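#' Unit conventions
#'
#' All heights are nanometres, times seconds, diffusion coefficients
#' um^2 s^-1, surface densities um^-2, energies multiples of kBT.
#' Conversions between nm and um are centralised here so that no
#' scattered factors of 1e-3 appear elsewhere.
#'
#' @name units
#' @keywords internal
NULL

nm_to_um <- function(x) x * 1e-3
um_to_nm <- function(x) x * 1e3

# Avogadro constant in molecules per micromole-litre scale:
# 1 mol/L = 6.02214076e23 / 1e15 molecules per um^3
molar_to_per_um3 <- function(molar) molar * 6.02214076e8

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(paste0("`", name, "` must be positive and finite."),
                 class = "heightspec_config_error")
  }
  invisible(x)
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    rlang::abort(paste0("`", name, "` must be non-negative and finite."),
                 class = "heightspec_config_error")
  }
  invisible(x)
}
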