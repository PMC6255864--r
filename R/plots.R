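#' Plot a height/time trace
#'
#' @param object An `afm_trace`.
#' @param threshold Optional [compute_threshold()] result drawn as a
#'   horizontal line.
#' @param max_points Traces longer than this are thinned for plotting.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.afm_trace <- function(object, threshold = NULL,
                               max_points = 2e5, ...) {
  df <- object
  if (nrow(df) > max_points) {
    df <- df[seq(1, nrow(df), length.out = max_points), ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$height_nm)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "height (nm)")
  if (!is.null(threshold)) {
    h <- if (is.data.frame(threshold)) threshold$h_t_nm else threshold
    p <- p + ggplot2::geom_hline(yintercept = h, linetype = 2,
                                 colour = "firebrick")
  }
  p
}

#' Plot a kymograph as a height raster
#'
#' @param object An `afm_kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.afm_kymograph <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$x_nm,
                               fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::labs(x = "time (s)", y = "x (nm)")
}

#' Plot a dwell-time histogram with its fitted Gaussian components
#'
#' @param object A [fit_dwell_mixture()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dwell_mixture <- function(object, ...) {
  edges <- object$edges
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  hist_df <- tibble::tibble(tau_us = centers * 1e6,
                            count = object$counts)
  grid <- seq(min(edges), max(edges), length.out = 400)
  comp <- object$components
  curves <- purrr::map_dfr(seq_len(nrow(comp)), function(k) {
    bw <- stats::median(diff(edges))
    tibble::tibble(component = factor(k), tau_us = grid * 1e6,
                   count = comp$amp[k] * bw *
                     stats::dnorm(grid, comp$mean_s[k], comp$sd_s[k]))
  })
  ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$tau_us,
                                        y = .data$count)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$component)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau[D] ~ "(us)"), y = "count")
}

#' Plot equilibrium oligomer mass fractions vs total concentration
#'
#' @param eq A tibble from [equilibrium_distribution()] evaluated on a
#'   concentration sweep.
#' @return A ggplot.
#' @export
plot_equilibrium <- function(eq) {
  df <- eq |>
    dplyr::group_by(.data$c_total, .data$class) |>
    dplyr::summarise(mass_fraction = sum(.data$mass_fraction),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c_total,
                                   y = .data$mass_fraction,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression("total surface concentration" ~
                                   (mu * m^-2)),
                  y = "mass fraction", colour = "oligomer")
}

#' Plot a two-state idealization over its trace
#'
#' @param object A [idealize_two_state()] result.
#' @param trace The trace it was fitted to.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.two_state_idealization <- function(object, trace = NULL, ...) {
  lv <- attr(object, "levels_nm")
  step_df <- tibble::tibble(
    time_s = as.vector(rbind(object$start_s, object$end_s)),
    height_nm = rep(ifelse(object$state == "high", lv[2], lv[1]),
                    each = 2))
  p <- ggplot2::ggplot()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_line(
      data = trace, ggplot2::aes(x = .data$time_s, y = .data$height_nm),
      colour = "lightblue", linewidth = 0.2)
  }
  p + ggplot2::geom_line(data = step_df,
                         ggplot2::aes(x = .data$time_s,
                                      y = .data$height_nm),
                         colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "height (nm)")
}
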