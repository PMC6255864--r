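#' Noise and z-feedback surrogates
#'
#' The instrument baseline is modelled as zero-mean Gaussian noise, added
#' independently per sample (default RMS 0.17 nm at 625 kHz). The z-piezo
#' feedback loop is modelled as a single-pole low-pass filter acting on
#' the ideal occupancy height signal before noise is added; its time
#' constant `tau_fb` sets the shortest detectable dwell. With the default
#' `tau_fb = 6 us` at 625 kHz sampling, a 2.7 us square occupancy pulse
#' of 2 nm never reaches the 5-sigma threshold of the default noise model
#' while pulses of 10 us and longer cross it essentially always --
#' reproducing the instrument's detectability boundary.
#'
#' @param sigma_nm RMS baseline noise, nm.
#' @param tau_fb_s Feedback response time constant, s.
#' @param sampling_rate Sampling rate, Hz.
#' @return `noise_model()` and `feedback_model()` return parameter lists.
#' @name feedback
NULL

#' @rdname feedback
#' @export
noise_model <- function(sigma_nm = 0.17) {
  stopifnot_positive(sigma_nm, "sigma_nm")
  structure(list(sigma_nm = sigma_nm), class = "noise_model")
}

#' @rdname feedback
#' @export
feedback_model <- function(tau_fb_s = 6e-6, sampling_rate = 625e3) {
  stopifnot_positive(tau_fb_s, "tau_fb_s")
  stopifnot_positive(sampling_rate, "sampling_rate")
  structure(list(tau_fb_s = tau_fb_s, sampling_rate = sampling_rate,
                 alpha = exp(-1 / (sampling_rate * tau_fb_s))),
            class = "feedback_model")
}

#' Apply the z-feedback surrogate to an ideal height signal
#'
#' Recursive single-pole low-pass: `y[i] = a y[i-1] + (1 - a) x[i]` with
#' `a = exp(-dt / tau_fb)`.
#'
#' @param x Ideal occupancy height signal, nm.
#' @param fb A [feedback_model()].
#' @param init Initial filter state, nm.
#' @return Filtered signal, same length as `x`.
#' @export
apply_feedback <- function(x, fb = feedback_model(), init = 0) {
  a <- fb$alpha
  y <- stats::filter(x * (1 - a), filter = a, method = "recursive",
                     init = init)
  as.numeric(y)
}

#' Peak filtered response to a square occupancy pulse
#'
#' Used to calibrate the detectability boundary: the noiseless peak of the
#' feedback-filtered response to a square pulse of the given duration.
#'
#' @param pulse_s Pulse duration, s.
#' @param height_nm Pulse height, nm.
#' @param fb A [feedback_model()].
#' @return Peak filtered height, nm.
#' @export
feedback_pulse_peak <- function(pulse_s, height_nm = 2.0, fb = feedback_model()) {
  n <- round(pulse_s * fb$sampling_rate)
  if (n < 1) return(0)
  height_nm * (1 - fb$alpha^n)
}
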