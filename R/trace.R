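#' Height/time trace container
#'
#' An `afm_trace` is a tibble with columns `time_s` and `height_nm`,
#' uniformly sampled, carrying the sampling rate (and, for synthetic
#' traces, ground truth) as attributes. All analysis functions accept
#' either an `afm_trace` or a plain data frame with those two columns
#' plus an explicit `sampling_rate`.
#'
#' @param height_nm Numeric vector of heights, nm.
#' @param sampling_rate Samples per second, Hz.
#' @param t0 Time of the first sample, s.
#' @param ground_truth Optional tibble of ground-truth annotations
#'   (occupancy intervals or state sequence) attached by simulators.
#' @param ... Further attributes to attach (e.g. `seed`, `config`).
#' @return A tibble of class `afm_trace`.
#' @export
new_afm_trace <- function(height_nm, sampling_rate, t0 = 0,
                          ground_truth = NULL, ...) {
  stopifnot_positive(sampling_rate, "sampling_rate")
  n <- length(height_nm)
  out <- tibble::tibble(
    time_s = t0 + (seq_len(n) - 1) / sampling_rate,
    height_nm = as.double(height_nm)
  )
  attr(out, "sampling_rate") <- sampling_rate
  if (!is.null(ground_truth)) attr(out, "ground_truth") <- ground_truth
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("afm_trace", class(out))
  out
}

#' @export
print.afm_trace <- function(x, ...) {
  cat(sprintf("<afm_trace> %d samples at %.6g Hz (%.4g s)\n",
              nrow(x), trace_sampling_rate(x), nrow(x) / trace_sampling_rate(x)))
  NextMethod()
}

#' Sampling rate of a trace
#'
#' @param trace An `afm_trace` or data frame with a `time_s` column.
#' @param sampling_rate Optional explicit override, Hz.
#' @return Sampling rate in Hz.
#' @export
trace_sampling_rate <- function(trace, sampling_rate = NULL) {
  if (!is.null(sampling_rate)) return(sampling_rate)
  sr <- attr(trace, "sampling_rate")
  if (!is.null(sr)) return(sr)
  if (!is.null(trace$time_s) && nrow(trace) > 1) {
    dt <- diff(trace$time_s)
    if (max(dt) - min(dt) > 1e-9 * stats::median(dt)) {
      rlang::abort("Trace timestamps are not uniform.",
                   class = "heightspec_format_error")
    }
    return(1 / stats::median(dt))
  }
  rlang::abort("Cannot determine sampling rate: supply `sampling_rate`.",
               class = "heightspec_format_error")
}

#' Ground truth attached to a synthetic trace or kymograph
#'
#' @param x A synthetic `afm_trace` or `afm_kymograph`.
#' @return The ground-truth tibble stored by the simulator, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")
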