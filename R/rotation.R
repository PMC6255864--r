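#' Two-state idealization of a telegraph height trace
#'
#' Boxcar-filters the trace (default 30 samples), locates the two state
#' levels as the two dominant modes of the filtered height distribution,
#' and assigns states by nearest level with hysteresis of half the level
#' separation (the signal must cross the midpoint by a quarter of the
#' separation to switch). Dwells shorter than the filter width are
#' retained. A trace whose filtered height distribution is not bimodal
#' raises a not-two-state error.
#'
#' @param trace An `afm_trace` or data frame with `height_nm`.
#' @param filter_width Boxcar width, samples.
#' @param debounce Minimum state persistence in samples; shorter
#'   excursions (noise spikes surviving the filter) are absorbed into
#'   their neighbours. By default chosen adaptively from the measured
#'   filtered-noise level: a third of the filter width when the switch
#'   threshold sits 5 or more filtered-noise s.d. from the levels,
#'   growing to twice the filter width for marginal signal-to-noise.
#' @param sampling_rate Override if `trace` carries none.
#' @return A `two_state_idealization`: tibble with one row per dwell
#'   (`state` = "low"/"high", `start_s`, `end_s`, `dwell_s`), attributes
#'   `levels_nm` (fitted state heights, low then high), `filter_width`,
#'   `sampling_rate` and `state_idx` (per-sample state, 0 = low).
#' @export
idealize_two_state <- function(trace, filter_width = 30,
                               debounce = NULL,
                               sampling_rate = NULL) {
  sr <- trace_sampling_rate(trace, sampling_rate)
  h <- trace$height_nm
  xf <- if (filter_width > 1) {
    as.numeric(stats::filter(h, rep(1 / filter_width, filter_width),
                             sides = 2))
  } else h
  xf[is.na(xf)] <- h[is.na(xf)]

  # level detection on filter-width-spaced (decorrelated) samples
  lv <- find_two_levels(xf[seq(1, length(xf), by = max(1, filter_width))])
  if (is.null(lv)) {
    rlang::abort("Height distribution is not two-state (unimodal).",
                 class = "heightspec_not_two_state")
  }
  sep <- diff(lv)
  mid <- mean(lv)
  hyst <- sep / 4
  if (is.null(debounce)) {
    # distance from a level to the far switch threshold, in units of the
    # filtered noise; marginal margins need longer persistence
    sigma_f <- stats::mad(xf - lv[1 + as.integer(
      abs(xf - lv[2]) < abs(xf - lv[1]))], constant = 1.4826)
    z <- (sep / 2 + hyst) / max(sigma_f, 1e-12)
    debounce <- if (z >= 5) floor(filter_width / 3)
                else if (z >= 3) filter_width
                else 2 * filter_width
  }
  s <- integer(length(xf))
  s[xf > mid + hyst] <- 1L
  s[xf < mid - hyst] <- -1L
  # carry the last decided state through the hysteresis band
  if (s[1] == 0L) s[1] <- if (xf[1] > mid) 1L else -1L
  idx <- cumsum(s != 0L)
  decided <- s[s != 0L]
  state <- decided[pmax(idx, 1L)]          # -1 = low, +1 = high
  state01 <- as.integer(state > 0)
  if (debounce > 1) state01 <- absorb_short_runs(state01, debounce)

  r <- rle(state01)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- tibble::tibble(
    state = ifelse(r$values == 1L, "high", "low"),
    start_s = (starts - 1) / sr,
    end_s = ends / sr,
    dwell_s = r$lengths / sr)
  # refine level estimates from the assigned samples
  lv <- c(mean(h[state01 == 0]), mean(h[state01 == 1]))
  attr(out, "levels_nm") <- lv
  attr(out, "filter_width") <- filter_width
  attr(out, "sampling_rate") <- sr
  attr(out, "state_idx") <- state01
  class(out) <- c("two_state_idealization", class(out))
  out
}

# flip state runs shorter than `debounce` into their neighbours
absorb_short_runs <- function(s, debounce, max_iter = 20) {
  for (i in seq_len(max_iter)) {
    r <- rle(s)
    if (length(r$lengths) <= 1) break
    short <- r$lengths < debounce
    short[c(1, length(short))] <- FALSE     # keep trace edges as observed
    if (!any(short)) break
    r$values[short] <- 1L - r$values[short]
    s <- inverse.rle(r)
  }
  s
}

# Two dominant levels of a distribution, or NULL if unimodal.
# Model-based: a two-component 1D Gaussian mixture must beat a single
# Gaussian by BIC. Near-noiseless traces with few distinct plateau values
# take a direct frequency path (mixture variances would degenerate).
find_two_levels <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || stats::sd(x) == 0) return(NULL)
  ux <- unique(round(x, 9))
  if (length(ux) <= 50) {
    # discrete trace (noiseless levels or grid-quantized positions):
    # the two levels are the two dominant values
    tab <- sort(table(round(x, 9)), decreasing = TRUE)
    if (length(tab) < 2) return(NULL)
    if (sum(tab[1:2]) >= 0.5 * length(x)) {
      return(sort(as.numeric(names(tab)[1:2])))
    }
    # otherwise fall through to the mixture-based path
  }
  # unambiguous separation: two tight clusters far apart (noise scales
  # where a mixture variance estimate would degenerate)
  qc <- unique(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  if (length(qc) == 2) {
    km <- tryCatch(stats::kmeans(x, centers = matrix(qc, ncol = 1)),
                   error = function(e) NULL)
    if (!is.null(km)) {
      within_sd <- sqrt(max(km$withinss / pmax(km$size - 1, 1)))
      ctr <- sort(as.vector(km$centers))
      if (diff(ctr) > 6 * max(within_sd, 1e-300) &&
          all(km$size > 0.02 * length(x))) {
        return(ctr)
      }
    }
  }
  xs <- x[unique(round(seq(1, length(x), length.out = 5000)))]
  fit <- tryCatch(
    mclust::Mclust(xs, G = 1:2, modelNames = c("E", "V"),
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || fit$G < 2) return(NULL)
  # demand strong evidence for two levels over one
  bic <- fit$BIC
  b1 <- suppressWarnings(max(bic[1, ], na.rm = TRUE))
  b2 <- suppressWarnings(max(bic[2, ], na.rm = TRUE))
  if (!is.finite(b1) || !is.finite(b2) || b2 - b1 < 10) return(NULL)
  lv <- sort(as.numeric(fit$parameters$mean))
  if (diff(lv) <= 0) return(NULL)
  lv
}

#' Dwell-time statistics of a two-state idealization
#'
#' @param idealization A [idealize_two_state()] result (or any data frame
#'   with `state` and `dwell_s`).
#' @param min_dwells Error below this many dwells.
#' @return A `dwell_stats` list: `per_state` tibble (mean, s.e.m., n per
#'   state and pooled) and `survival` tibble (`state`, `t_s`,
#'   `survival`), the empirical survival function of the pooled dwells.
#' @export
dwell_statistics <- function(idealization, min_dwells = 10) {
  dw <- idealization
  if (nrow(dw) < min_dwells) {
    rlang::abort(sprintf("Only %d dwells (need >= %d).", nrow(dw),
                         min_dwells),
                 class = "heightspec_data_error")
  }
  per <- dw |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(mean_s = mean(.data$dwell_s),
                     sem_s = stats::sd(.data$dwell_s) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  pooled <- tibble::tibble(state = "pooled", mean_s = mean(dw$dwell_s),
                           sem_s = stats::sd(dw$dwell_s) / sqrt(nrow(dw)),
                           n = nrow(dw))
  ts <- sort(dw$dwell_s)
  surv <- tibble::tibble(state = "pooled", t_s = ts,
                         survival = 1 - seq_along(ts) / length(ts))
  structure(list(per_state = dplyr::bind_rows(per, pooled),
                 survival = surv),
            class = "dwell_stats")
}

#' @export
print.dwell_stats <- function(x, ...) {
  print(x$per_state)
  invisible(x)
}

#' @export
tidy.dwell_stats <- function(x, ...) x$per_state

#' Height/time traces at the two state positions of a kymograph
#'
#' Extracts the height/time traces at the scan positions corresponding to
#' the two orientations (one sample per line), forms their difference --
#' the two positions are anti-correlated, so subtraction amplifies the
#' signal while cancelling correlated errors -- and idealizes the
#' difference trace with the two-state machinery.
#'
#' @param kym An `afm_kymograph`.
#' @param x0_nm,x60_nm Scan positions of the two orientations, nm
#'   (default: the simulator's plateau lobe positions when available).
#' @param filter_width Boxcar width (lines) for the difference-trace
#'   idealization.
#' @return A `kymo_state_traces` list: `traces` tibble (`time_s`,
#'   `h0_nm`, `h60_nm`, `diff_nm`), `idealization` of the difference
#'   trace, `correlation` (Pearson r between the two traces).
#' @export
extract_position_traces <- function(kym, x0_nm = NULL, x60_nm = NULL,
                                    filter_width = 3) {
  x <- attr(kym, "x_nm")
  if (is.null(x0_nm) || is.null(x60_nm)) {
    sx <- attr(kym, "state_x_nm")
    if (is.null(sx)) {
      rlang::abort("Supply `x0_nm` and `x60_nm`.",
                   class = "heightspec_config_error")
    }
    x0_nm <- x0_nm %||% sx[1]
    x60_nm <- x60_nm %||% sx[2]
  }
  if (x0_nm < min(x) || x0_nm > max(x) || x60_nm < min(x) ||
      x60_nm > max(x)) {
    rlang::abort("Requested positions are outside the kymograph.",
                 class = "heightspec_config_error")
  }
  r0 <- which.min(abs(x - x0_nm))
  r60 <- which.min(abs(x - x60_nm))
  lp <- attr(kym, "line_period_s")
  traces <- tibble::tibble(
    time_s = (seq_len(ncol(kym)) - 0.5) * lp,
    h0_nm = kym[r0, ], h60_nm = kym[r60, ],
    diff_nm = kym[r0, ] - kym[r60, ])
  ideal <- idealize_two_state(
    tibble::tibble(height_nm = traces$diff_nm),
    filter_width = filter_width, sampling_rate = 1 / lp)
  structure(list(traces = traces, idealization = ideal,
                 correlation = stats::cor(traces$h0_nm, traces$h60_nm)),
            class = "kymo_state_traces")
}

#' @export
print.kymo_state_traces <- function(x, ...) {
  cat(sprintf("<kymo_state_traces> %d lines, r = %.3f, %d dwells\n",
              nrow(x$traces), x$correlation, nrow(x$idealization)))
  invisible(x)
}

#' Measure rotation transitions on a kymograph
#'
#' Tracks the visible lobe position line by line (intensity-weighted
#' argmax over the central, flickering rows), identifies the two plateau
#' positions, and delimits each transition by the lobe leaving one
#' plateau band and arriving in the other. The duration is the
#' transition line count times the line period (quantized to +-1 line);
#' the direction is the sign of the summed lobe-position increments over
#' the transition, taken modulo the lattice period `2 * delta` so that a
#' lobe wrapping out one side and in the other still reports a coherent
#' direction. Transitions touching the trace edges are discarded and
#' counted.
#'
#' @param kym An `afm_kymograph`.
#' @param plateau_tol_nm Half-width of the plateau bands; default a
#'   quarter of the plateau separation.
#' @return Tibble, one row per resolved transition: `line_start`,
#'   `line_end`, `t_start_s`, `duration_s`, `n_lines`, `direction` (+1
#'   CCW / -1 CW), `from_x_nm`, `to_x_nm`; attribute `n_discarded_edge`.
#' @export
measure_rotation_transitions <- function(kym, plateau_tol_nm = NULL) {
  x <- attr(kym, "x_nm")
  lp <- attr(kym, "line_period_s")
  delta <- attr(kym, "delta_nm")
  # flickering central rows: exclude stationary flanking ridges
  row_sd <- apply(kym, 1, stats::sd)
  central <- if (!is.null(delta)) abs(x) <= delta else
    row_sd > 0.5 * max(row_sd)
  sub <- kym[central, , drop = FALSE]
  xs <- x[central]
  # lobe position per line: brightest row; a lobe handing over to its
  # symmetry partner jumps by exactly one lattice period, which the
  # wrapped difference cancels
  p <- xs[apply(sub, 2, which.max)]
  if (length(p) >= 3) p <- stats::runmed(p, 3)

  lv <- find_two_levels(p)
  if (is.null(lv)) {
    rlang::abort("No two-position flicker found in the kymograph.",
                 class = "heightspec_not_two_state")
  }
  x_step <- attr(kym, "x_step_nm") %||% stats::median(diff(sort(unique(xs))))
  tol <- plateau_tol_nm %||% max(0.6 * x_step, 0.05 * diff(lv))
  near0 <- abs(p - lv[1]) < tol
  near1 <- abs(p - lv[2]) < tol
  plateau <- ifelse(near0, 0L, ifelse(near1, 1L, NA_integer_))

  period <- if (!is.null(delta)) 2 * delta else 2 * diff(lv)
  wrap <- function(d) (d + period / 2) %% period - period / 2

  n <- length(p)
  known <- which(!is.na(plateau))
  trans <- list()
  # a transition underway at either trace edge cannot be delimited
  discarded <- sum(is.na(plateau[1]), is.na(plateau[n]))
  if (length(known) >= 2) {
    for (i in seq_len(length(known) - 1)) {
      a <- known[i]; b <- known[i + 1]
      if (plateau[a] == plateau[b]) next
      n_lines <- b - a
      seg <- p[a:b]
      dirsum <- sum(wrap(diff(seg)))
      trans[[length(trans) + 1]] <- tibble::tibble(
        line_start = a, line_end = b,
        t_start_s = (a - 0.5) * lp,
        duration_s = n_lines * lp, n_lines = n_lines,
        direction = ifelse(dirsum >= 0, 1L, -1L),
        from_x_nm = lv[plateau[a] + 1], to_x_nm = lv[plateau[b] + 1],
        resolvable = n_lines > 1)
    }
  }
  out <- if (length(trans)) dplyr::bind_rows(trans) else
    tibble::tibble(line_start = integer(0), line_end = integer(0),
                   t_start_s = numeric(0), duration_s = numeric(0),
                   n_lines = integer(0), direction = integer(0),
                   from_x_nm = numeric(0), to_x_nm = numeric(0),
                   resolvable = logical(0))
  attr(out, "n_discarded_edge") <- discarded
  attr(out, "plateau_x_nm") <- lv
  out
}

#' Rotation energetics from state and transition times
#'
#' The free-energy barrier separating the two orientations is estimated
#' from the ratio of the mean time spent rotating to the mean time spent
#' waiting in a state, `Delta G = -ln(tau_rotation / tau_state)` in kBT;
#' the angular velocity of a single 60-degree step is
#' `60 / tau_rotation` degrees per second.
#'
#' @param tau_state_s Mean state dwell, s.
#' @param tau_rotation_s Mean rotation (transition) time, s.
#' @return One-row tibble: `delta_g_kbt`, `angular_velocity_deg_s`,
#'   `rpm`.
#' @examples
#' rotation_energetics(0.035, 0.018)  # ~0.7 kBT, ~3300 deg/s, ~550 rpm
#' @export
rotation_energetics <- function(tau_state_s, tau_rotation_s) {
  stopifnot_positive(tau_state_s, "tau_state_s")
  stopifnot_positive(tau_rotation_s, "tau_rotation_s")
  v <- 60 / tau_rotation_s
  tibble::tibble(delta_g_kbt = -log(tau_rotation_s / tau_state_s),
                 angular_velocity_deg_s = v, rpm = v / 6)
}
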