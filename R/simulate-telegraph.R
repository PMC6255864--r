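#' Configure a two-state telegraph trace
#'
#' Models the height/time signal of a trimer rotating between two
#' preferred orientations: two height levels (defaults 2.00 and 1.72 nm),
#' exponentially distributed state dwells, linear height ramps of fixed
#' duration during the transitions, a per-dwell height jitter (the
#' molecule does not sit at exactly the same height each visit) and
#' Gaussian per-sample noise added last.
#'
#' @param heights_nm Heights of the two states, nm (high state first).
#' @param mean_dwell_s Mean state dwell per state, s (recycled).
#' @param transition_s Duration of the linear transition ramp, s.
#' @param jitter_nm Per-dwell height jitter s.d. per state, nm.
#' @param noise A [noise_model()] (per-sample noise).
#' @param seed Optional RNG seed.
#' @return A `telegraph_config` list.
#' @export
telegraph_config <- function(heights_nm = c(2.00, 1.72),
                             mean_dwell_s = 0.030,
                             transition_s = 0.018,
                             jitter_nm = c(0.10, 0.07),
                             noise = noise_model(),
                             seed = NULL) {
  if (length(heights_nm) != 2 || heights_nm[1] == heights_nm[2]) {
    rlang::abort("`heights_nm` must be two distinct levels.",
                 class = "heightspec_config_error")
  }
  mean_dwell_s <- rep_len(mean_dwell_s, 2)
  stopifnot_positive(mean_dwell_s, "mean_dwell_s")
  stopifnot_nonneg(transition_s, "transition_s")
  jitter_nm <- rep_len(jitter_nm, 2)
  stopifnot_nonneg(jitter_nm, "jitter_nm")
  structure(list(heights_nm = heights_nm, mean_dwell_s = mean_dwell_s,
                 transition_s = transition_s, jitter_nm = jitter_nm,
                 noise = noise, seed = seed),
            class = "telegraph_config")
}

#' Simulate a two-state telegraph height trace
#'
#' @param config A [telegraph_config()].
#' @param duration_s Trace duration, s.
#' @param sampling_rate Sampling rate, Hz.
#' @return An [new_afm_trace()] whose `ground_truth` attribute holds the
#'   state sequence: one row per plateau (`state` = 1 for the first /
#'   high level, 2 for the second; `start_s`, `end_s`, `level_nm`), with
#'   ramps occupying the gaps between consecutive plateaus.
#' @export
simulate_telegraph_trace <- function(config, duration_s,
                                     sampling_rate = 625e3) {
  stopifnot(inherits(config, "telegraph_config"))
  stopifnot_positive(duration_s, "duration_s")
  stopifnot_positive(sampling_rate, "sampling_rate")
  if (!is.null(config$seed)) set.seed(config$seed)

  # draw alternating dwells until the duration is covered
  states <- integer(0); dwells <- numeric(0)
  s <- 1L; t <- 0
  while (t < duration_s) {
    d <- stats::rexp(1, 1 / config$mean_dwell_s[s])
    states <- c(states, s); dwells <- c(dwells, d)
    t <- t + d + config$transition_s
    s <- 3L - s
  }
  k <- length(states)
  levels <- config$heights_nm[states] +
    stats::rnorm(k, 0, config$jitter_nm[states])

  start_s <- cumsum(c(0, dwells[-k] + config$transition_s))
  end_s <- start_s + dwells
  gt <- tibble::tibble(state = states, start_s = start_s, end_s = end_s,
                       level_nm = levels)

  # piecewise-linear ideal signal: constant on plateaus, linear ramps
  if (config$transition_s > 0) {
    knots_t <- as.vector(rbind(start_s, end_s))
    knots_h <- as.vector(rbind(levels, levels))
  } else {
    eps <- 1 / (sampling_rate * 1e3)
    knots_t <- as.vector(rbind(start_s + eps, end_s))
    knots_h <- as.vector(rbind(levels, levels))
  }
  n <- round(duration_s * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate
  ideal <- stats::approx(knots_t, knots_h, xout = tt, rule = 2)$y
  heights <- ideal + stats::rnorm(n, 0, config$noise$sigma_nm)
  new_afm_trace(heights, sampling_rate, ground_truth = gt,
                config = config, seed = config$seed)
}
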