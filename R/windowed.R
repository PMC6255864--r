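#' Windowed time-lapse analysis of a height trace
#'
#' Splits the trace into consecutive half-open windows `[k*w, (k+1)*w)`
#' (default 1 s) and reports, per window, the event count rate, the mean
#' dwell time, the occupancy-derived surface concentration, and -- when a
#' fitted dwell mixture is supplied -- the unit-weighted oligomer-class
#' fractions. Events are assigned to the window containing their start
#' time. Only complete windows are reported.
#'
#' @param trace An `afm_trace` or data frame with `height_nm`.
#' @param threshold A [compute_threshold()] result or threshold in nm.
#' @param d_p_nm Molecular footprint for the concentration, nm.
#' @param window_s Window length, s (default 1).
#' @param mixture Optional [fit_dwell_mixture()] for per-window oligomer
#'   fractions.
#' @param sampling_rate Override if `trace` carries none.
#' @return Tibble, one row per window: `window`, `t_start_s`, `n_events`,
#'   `event_rate_per_s`, `mean_dwell_s`, `c_um2`, and `frac_1`..`frac_o`
#'   when `mixture` is given.
#' @export
windowed_analysis <- function(trace, threshold, d_p_nm, window_s = 1,
                              mixture = NULL, sampling_rate = NULL) {
  sr <- trace_sampling_rate(trace, sampling_rate)
  t_total <- nrow(trace) / sr
  if (window_s > t_total) {
    rlang::abort("Window longer than the trace.",
                 class = "heightspec_data_error")
  }
  n_win <- floor(t_total / window_s)
  if (n_win < 2) {
    rlang::abort("Trace must span at least two windows.",
                 class = "heightspec_data_error")
  }
  ev <- detect_events(trace, threshold, sampling_rate = sr)
  if (!is.null(mixture)) ev <- classify_events(ev, mixture)
  ev$window <- floor(ev$start_s / window_s)
  ev <- dplyr::filter(ev, .data$window < n_win)
  d_p_um2 <- nm_to_um(d_p_nm)^2

  base <- tibble::tibble(window = seq_len(n_win) - 1)
  summ <- ev |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(n_events = dplyr::n(),
                     mean_dwell_s = mean(.data$dwell_s),
                     t_above_s = sum(.data$dwell_s), .groups = "drop")
  out <- dplyr::left_join(base, summ, by = "window") |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      t_above_s = dplyr::coalesce(.data$t_above_s, 0),
      t_start_s = .data$window * window_s,
      event_rate_per_s = .data$n_events / window_s,
      c_um2 = .data$t_above_s / window_s / d_p_um2) |>
    dplyr::select("window", "t_start_s", "n_events", "event_rate_per_s",
                  "mean_dwell_s", "c_um2")

  if (!is.null(mixture)) {
    classes <- c(as.character(1:4), "o")
    fr <- ev |>
      dplyr::mutate(units = .data$species) |>
      dplyr::group_by(.data$window, .data$species_class) |>
      dplyr::summarise(u = sum(.data$units), .groups = "drop_last") |>
      dplyr::mutate(frac = .data$u / sum(.data$u)) |>
      dplyr::ungroup() |>
      dplyr::select("window", "species_class", "frac") |>
      tidyr::pivot_wider(names_from = "species_class",
                         values_from = "frac", names_prefix = "frac_")
    for (cc in classes) {
      nm <- paste0("frac_", cc)
      if (!nm %in% names(fr)) fr[[nm]] <- 0
    }
    out <- dplyr::left_join(out, fr, by = "window")
    for (cc in classes) {
      nm <- paste0("frac_", cc)
      out[[nm]][is.na(out[[nm]]) & out$n_events > 0] <- 0
    }
  }
  out
}
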