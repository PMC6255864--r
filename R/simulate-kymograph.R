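#' Rotation schedule for a kymograph simulation
#'
#' Describes alternating holds and 60-degree rotations of the weakly bound
#' trimer sitting on the 6-fold axis of the 2D lattice. The trimer holds
#' each orientation for the given dwell, then rotates 60 degrees clockwise
#' (`direction = -1`) or counter-clockwise (`+1`) over `transition_s` at
#' constant angular velocity.
#'
#' @param state_dwell_s Dwell time in each successive orientation, s.
#' @param direction Rotation direction of each transition (+1 CCW,
#'   -1 CW); length one less than `state_dwell_s`.
#' @param transition_s Rotation duration, s (default 18 ms).
#' @return A tibble of segments (`type`, `t_start_s`, `t_end_s`,
#'   `theta_start`, `theta_end`, `state`, `direction`) of class
#'   `rotation_schedule`, where `state` is 0 or 60 (degrees) on plateaus.
#' @export
rotation_schedule <- function(state_dwell_s, direction = integer(0),
                              transition_s = 0.018) {
  if (length(state_dwell_s) == 0) {
    rlang::abort("Empty rotation schedule.", class = "heightspec_config_error")
  }
  stopifnot_positive(state_dwell_s, "state_dwell_s")
  stopifnot_nonneg(transition_s, "transition_s")
  if (length(direction) != length(state_dwell_s) - 1) {
    rlang::abort("`direction` must have one entry per transition.",
                 class = "heightspec_config_error")
  }
  if (length(direction) && !all(direction %in% c(-1, 1))) {
    rlang::abort("`direction` entries must be +1 (CCW) or -1 (CW).",
                 class = "heightspec_config_error")
  }
  theta <- cumsum(c(0, 60 * direction))
  seg <- list(); t <- 0
  for (i in seq_along(state_dwell_s)) {
    seg[[length(seg) + 1]] <- tibble::tibble(
      type = "state", t_start_s = t, t_end_s = t + state_dwell_s[i],
      theta_start = theta[i], theta_end = theta[i],
      state = ((theta[i] %% 120) + 120) %% 120, direction = 0)
    t <- t + state_dwell_s[i]
    if (i < length(state_dwell_s)) {
      seg[[length(seg) + 1]] <- tibble::tibble(
        type = "transition", t_start_s = t, t_end_s = t + transition_s,
        theta_start = theta[i], theta_end = theta[i + 1],
        state = NA_real_, direction = direction[i])
      t <- t + transition_s
    }
  }
  out <- dplyr::bind_rows(seg)
  class(out) <- c("rotation_schedule", class(out))
  out
}

#' Simulate a line-scan kymograph of a rotating trimer
#'
#' The three lobes of the trimer are projected onto the scan line in
#' unrolled-arc coordinates: lobes sit on a circle of radius
#' `lobe_radius_nm`, so a 60-degree rotation displaces the visible lobe by
#' `delta = lobe_radius * pi/3` (about 3 nm with the defaults) along the
#' scan, and the three-fold symmetry repeats lobes every `2 * delta`.
#' Exactly one lobe is visible in the central window at a time; lobes
#' leaving the window fade (occluded by the surrounding lattice). Two
#' stationary ridges flank the window, mimicking the stable neighbouring
#' trimers of the lattice. Clockwise and counter-clockwise rotations
#' between the same two orientations produce mirror-image diagonal
#' streaks.
#'
#' @param schedule A [rotation_schedule()].
#' @param line_period_s Time per scan line, s (default 2.4 ms).
#' @param x_step_nm Pixel size along the scan line, nm.
#' @param lobe_radius_nm Radius of the lobe circle, nm.
#' @param lobe_sigma_nm Gaussian width of a lobe profile, nm.
#' @param peak_nm Lobe peak height, nm.
#' @param x_span_nm Half-width of the rendered scan line, nm.
#' @param ridge_x_nm Positions of the two stationary flanking ridges, nm.
#' @param noise A [noise_model()]; per-pixel Gaussian noise (line scans
#'   average over the pixel dwell, so the default is below the 625 kHz
#'   baseline RMS).
#' @param seed Optional RNG seed.
#' @return An `afm_kymograph`: height matrix (rows = x positions, columns
#'   = successive lines) with attributes `x_nm`, `line_period_s`,
#'   `ground_truth` (the schedule), `delta_nm` and `state_x_nm` (the two
#'   plateau lobe positions).
#' @export
simulate_rotation_kymograph <- function(schedule,
                                        line_period_s = 2.4e-3,
                                        x_step_nm = 0.5,
                                        lobe_radius_nm = 2.9,
                                        lobe_sigma_nm = 1.1,
                                        peak_nm = 2.0,
                                        x_span_nm = 8,
                                        ridge_x_nm = c(-6, 6),
                                        noise = noise_model(0.1),
                                        seed = NULL) {
  if (!inherits(schedule, "rotation_schedule") || nrow(schedule) == 0) {
    rlang::abort("`schedule` must be a non-empty rotation_schedule.",
                 class = "heightspec_config_error")
  }
  stopifnot_positive(line_period_s, "line_period_s")
  if (!is.null(seed)) set.seed(seed)

  delta <- lobe_radius_nm * pi / 3
  x <- seq(-x_span_nm, x_span_nm, by = x_step_nm)
  total_t <- max(schedule$t_end_s)
  n_lines <- floor(total_t / line_period_s)
  t_mid <- (seq_len(n_lines) - 0.5) * line_period_s

  # piecewise-linear orientation vs time from the schedule
  knots_t <- as.vector(rbind(schedule$t_start_s, schedule$t_end_s))
  knots_th <- as.vector(rbind(schedule$theta_start, schedule$theta_end))
  theta <- stats::approx(knots_t, knots_th, xout = t_mid, rule = 2,
                         ties = "ordered")$y

  theta_w <- ((theta %% 120) + 120) %% 120
  q <- lobe_radius_nm * theta_w * pi / 180          # in [0, 2*delta)
  ridge_prof <- rowSums(vapply(ridge_x_nm, function(r)
    peak_nm * exp(-(x - r)^2 / (2 * lobe_sigma_nm^2)), numeric(length(x))))

  mat <- matrix(0, nrow = length(x), ncol = n_lines)
  fade_sigma <- 0.8
  for (l in seq_len(n_lines)) {
    prof <- ridge_prof
    for (k in -1:1) {
      p <- q[l] - delta / 2 + 2 * k * delta
      over <- max(0, abs(p) - delta)
      amp <- peak_nm * exp(-over^2 / (2 * fade_sigma^2))
      prof <- prof + amp * exp(-(x - p)^2 / (2 * lobe_sigma_nm^2))
    }
    mat[, l] <- prof
  }
  if (noise$sigma_nm > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), 0, noise$sigma_nm),
                        nrow = nrow(mat))
  }
  structure(mat,
            x_nm = x, line_period_s = line_period_s, x_step_nm = x_step_nm,
            ground_truth = schedule, delta_nm = delta,
            state_x_nm = c(-delta / 2, delta / 2),
            lobe_sigma_nm = lobe_sigma_nm, noise_sigma_nm = noise$sigma_nm,
            seed = seed,
            class = c("afm_kymograph", "matrix", "array"))
}

#' @export
print.afm_kymograph <- function(x, ...) {
  cat(sprintf("<afm_kymograph> %d x-positions x %d lines (%.3g ms/line)\n",
              nrow(x), ncol(x), attr(x, "line_period_s") * 1e3))
  invisible(x)
}

#' Convert a kymograph to a long tibble
#'
#' @param x An `afm_kymograph`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `x_nm`, `height_nm`.
#' @export
as_tibble.afm_kymograph <- function(x, ...) {
  tibble::tibble(
    time_s = rep((seq_len(ncol(x)) - 0.5) * attr(x, "line_period_s"),
                 each = nrow(x)),
    x_nm = rep(attr(x, "x_nm"), ncol(x)),
    height_nm = as.vector(x)
  )
}
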