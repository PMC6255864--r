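#' Multi-Gaussian deconvolution of a dwell-time distribution
#'
#' Histograms the event dwell times (Freedman-Diaconis binning on the
#' log-dwell axis by default) and fits the binned counts with sums of
#' 1..`n_max` Gaussian peaks by Poisson-weighted least squares, each peak
#' with a free amplitude (which makes the fit robust to the censoring of
#' dwells below the detectability floor). Sparse bins are merged until
#' each holds at least five events, keeping the chi-squared weighting
#' valid in the tails. The component count is selected
#' by reduced chi-squared: the smallest number of components within 8% of
#' the minimal reduced chi-squared, so that extra components must earn
#' their parameters. The fit is deterministic: a fixed schedule of
#' starting values (dwell quantiles, multiples of the histogram density
#' mode, and the best fit with one fewer component plus a new peak) is
#' tried for each candidate count. Each peak corresponds to one
#' oligomeric species: dwell time grows with oligomer footprint, so
#' successive peaks map to successive oligomer sizes. Where components
#' overlap strongly, the mean of the uppermost component is only weakly
#' identified (see the package vignette).
#'
#' @param events A `dwell_set` (or data frame with `dwell_s`), or a
#'   numeric vector of dwell times in seconds.
#' @param n_max Largest number of components to try.
#' @param edges Optional histogram bin edges (s); default Freedman-
#'   Diaconis on log10(dwell).
#' @param min_events Below this many dwells, fall back to a single
#'   component with a warning.
#' @return A `dwell_mixture` object; see [tidy.dwell_mixture()] /
#'   [glance.dwell_mixture()].
#' @export
fit_dwell_mixture <- function(events, n_max = 5, edges = NULL,
                              min_events = 50) {
  dwell <- if (is.numeric(events)) events else events$dwell_s
  if (length(dwell) == 0) {
    rlang::abort("No dwell times to fit.", class = "heightspec_data_error")
  }
  stopifnot_positive(dwell, "dwell times")
  if (length(dwell) < min_events && n_max > 1) {
    rlang::warn(sprintf(
      "Only %d dwells: falling back to a single-component fit.",
      length(dwell)))
    n_max <- 1
  }
  user_edges <- !is.null(edges)
  if (!user_edges) edges <- fd_log_edges(dwell)
  counts <- graphics::hist(dwell, breaks = edges, plot = FALSE)$counts
  if (!user_edges) {
    # merge sparse bins so the Poisson chi-squared weighting is valid
    mb <- merge_sparse_bins(edges, counts)
    edges <- mb$edges
    counts <- mb$counts
  }
  nb <- length(counts)

  fits <- vector("list", n_max)
  prev <- NULL
  for (k in seq_len(n_max)) {
    if (nb - 3 * k < 2) break
    fits[[k]] <- fit_gauss_sum(dwell, edges, counts, k, prev)
    if (!is.null(fits[[k]]) && is.finite(fits[[k]]$redchi)) {
      prev <- fits[[k]]$components
    }
  }
  redchi <- vapply(fits, function(f) if (is.null(f)) Inf else f$redchi, 0)
  if (all(!is.finite(redchi))) {
    # too few usable bins for a histogram fit: fall back to moments
    fits[[1]] <- list(redchi = NA_real_, components = tibble::tibble(
      component = 1L, mean_s = mean(dwell), sd_s = stats::sd(dwell),
      amp = length(dwell), weight = 1))
    redchi <- c(NA_real_, rep(Inf, length(fits) - 1))[seq_along(fits)]
    best <- 1L
    return(structure(list(components = fits[[1]]$components,
                          n_components = 1L,
                          reduced_chisq = NA_real_,
                          candidates = tibble::tibble(
                            n_components = seq_along(redchi),
                            reduced_chisq = redchi),
                          edges = edges, counts = counts,
                          n_dwells = length(dwell)),
                     class = "dwell_mixture"))
  }
  # smallest component count within 8% of the minimal reduced chi-squared
  best <- which(redchi <= min(redchi) * 1.08)[1]
  structure(list(components = fits[[best]]$components,
                 n_components = best,
                 reduced_chisq = redchi[best],
                 candidates = tibble::tibble(
                   n_components = seq_along(redchi),
                   reduced_chisq = redchi),
                 edges = edges, counts = counts,
                 n_dwells = length(dwell)),
            class = "dwell_mixture")
}

# merge adjacent bins until every bin holds at least `min_count` events
merge_sparse_bins <- function(edges, counts, min_count = 5) {
  out_counts <- integer(0)
  out_edges <- edges[1]
  acc <- 0
  for (i in seq_along(counts)) {
    acc <- acc + counts[i]
    if (acc >= min_count || i == length(counts)) {
      out_counts <- c(out_counts, acc)
      out_edges <- c(out_edges, edges[i + 1])
      acc <- 0
    }
  }
  nb <- length(out_counts)
  if (nb > 1 && out_counts[nb] < min_count) {
    out_counts[nb - 1] <- out_counts[nb - 1] + out_counts[nb]
    out_counts <- out_counts[-nb]
    out_edges <- out_edges[-nb]
  }
  list(edges = out_edges, counts = out_counts)
}

# Freedman-Diaconis bin edges on the log10-dwell axis
fd_log_edges <- function(dwell) {
  ld <- log10(dwell)
  bw <- 2 * stats::IQR(ld) / length(ld)^(1 / 3)
  rng <- range(ld)
  if (bw <= 0 || !is.finite(bw)) bw <- diff(rng) / max(8, sqrt(length(ld)))
  if (bw <= 0 || diff(rng) == 0) {
    return(10^seq(rng[1] - 0.05, rng[2] + 0.05, length.out = 9))
  }
  nb <- max(8, ceiling(diff(rng) / bw))
  10^seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = nb + 1)
}

# expected bin contents for a sum of Gaussian peaks with free areas
gauss_sum_expected <- function(edges, mu, sd, area) {
  sd <- pmax(sd, 1e-300)
  e <- outer(edges, mu, function(x, m) x - m)
  cdf <- stats::pnorm(sweep(e, 2, sd, "/"))
  as.vector((cdf[-1, , drop = FALSE] -
             cdf[-nrow(cdf), , drop = FALSE]) %*% area)
}

fit_gauss_sum <- function(dwell, edges, counts, k, prev = NULL) {
  nb <- length(counts)
  # a component narrower than a histogram bin is meaningless
  sd_min <- 0.5 * stats::median(diff(edges))
  # peak means confined to the observed dwell range: an out-of-range
  # component has an unconstrained amplitude
  mu_lo <- 0
  mu_hi <- 1.1 * max(dwell)
  mu_fwd <- function(p) mu_lo + (mu_hi - mu_lo) * stats::plogis(p)
  mu_inv <- function(m) stats::qlogis(pmin(pmax(
    (m - mu_lo) / (mu_hi - mu_lo), 1e-6), 1 - 1e-6))
  obj <- function(par) {
    mu <- mu_fwd(par[1:k])
    sd <- sd_min + exp(par[k + 1:k])
    amp <- exp(par[2 * k + 1:k])
    e <- gauss_sum_expected(edges, mu, sd, amp)
    sum((counts - e)^2 / pmax(e, 0.5))
  }
  n <- length(dwell)
  s0 <- max(stats::sd(dwell) / k, 2 * sd_min)
  dens <- counts / diff(edges)
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  mode_d <- centers[which.max(dens)]
  q <- stats::quantile(dwell, probs = (seq_len(k) - 0.5) / k,
                       names = FALSE)
  starts <- list(
    list(mu = q, sd = rep(s0, k), amp = rep(n / k, k)),
    list(mu = mode_d * seq_len(k), sd = rep(s0, k), amp = rep(n / k, k)))
  if (k > 1) {
    km <- tryCatch(stats::kmeans(dwell, centers = matrix(q, ncol = 1)),
                   error = function(e) NULL)
    if (!is.null(km)) {
      ord <- order(km$centers)
      km_sd <- vapply(ord, function(j) {
        v <- dwell[km$cluster == j]
        if (length(v) > 1) stats::sd(v) else s0
      }, 0)
      starts <- c(starts, list(list(
        mu = as.vector(km$centers)[ord],
        sd = pmax(km_sd, 2 * sd_min),
        amp = km$size[ord])))
    }
  }
  if (!is.null(prev) && nrow(prev) == k - 1) {
    starts <- c(starts, list(list(
      mu = c(prev$mean_s, max(prev$mean_s) * 1.7),
      sd = c(prev$sd_s, s0),
      amp = c(prev$amp, n / (2 * k)))))
  }
  best <- NULL
  for (st in starts) {
    par0 <- c(mu_inv(st$mu),
              log(pmax(st$sd - sd_min, sd_min / 10)),
              log(pmax(st$amp, 1)))
    f <- tryCatch(stats::optim(par0, obj, method = "BFGS",
                               control = list(maxit = 1000)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) return(NULL)
  mu <- mu_fwd(best$par[1:k])
  sd <- sd_min + exp(best$par[k + 1:k])
  amp <- exp(best$par[2 * k + 1:k])
  ord <- order(mu)
  mu <- mu[ord]; sd <- sd[ord]; amp <- amp[ord]
  if (k > 1 && any(diff(mu) / mu[-k] < 1e-6)) {
    return(list(redchi = Inf, components = NULL))  # collapsed means
  }
  list(redchi = best$value / (nb - 3 * k),
       components = tibble::tibble(component = seq_len(k), mean_s = mu,
                                   sd_s = sd, amp = amp,
                                   weight = amp / sum(amp)))
}

#' @export
print.dwell_mixture <- function(x, ...) {
  cat(sprintf(
    "<dwell_mixture> %d component(s) over %d dwells, reduced chi^2 = %.3g\n",
    x$n_components, x$n_dwells, x$reduced_chisq))
  print(x$components)
  invisible(x)
}

#' Tidy a dwell-time mixture fit
#'
#' @param x A `dwell_mixture`.
#' @param ... Unused.
#' @return One row per Gaussian component (`component`, `mean_s`, `sd_s`,
#'   `weight`).
#' @export
tidy.dwell_mixture <- function(x, ...) {
  dplyr::select(x$components, "component", "mean_s", "sd_s", "weight")
}

#' @rdname tidy.dwell_mixture
#' @export
glance.dwell_mixture <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 reduced_chisq = x$reduced_chisq,
                 n_dwells = x$n_dwells)
}

#' Assign events to oligomer species from a fitted mixture
#'
#' Each event is assigned to the mixture component with the largest
#' posterior responsibility at its dwell time; the decision boundaries
#' are the equal-responsibility crossings between adjacent components,
#' and exact ties break to the smaller component. Component `i` is taken
#' to carry `i` trimer units; components of 5 or more units are pooled
#' into the class `"o"`. The returned fraction vector is the
#' unit-weighted (mass) fraction of trimers in each class, accumulated
#' from the posterior responsibilities (soft assignment), which stays
#' unbiased where components overlap; the per-event labels use the hard
#' maximum-responsibility assignment.
#'
#' @param events A `dwell_set` or data frame with `dwell_s`.
#' @param mixture A fitted [fit_dwell_mixture()].
#' @return `events` with added columns `species` (component index) and
#'   `species_class` ("1".."4" or "o"), and attribute `fractions` (named
#'   mass-fraction vector over classes 1..4 and "o").
#' @export
classify_events <- function(events, mixture) {
  if (!inherits(mixture, "dwell_mixture") || is.null(mixture$components)) {
    rlang::abort("`mixture` must be a fitted dwell_mixture.",
                 class = "heightspec_data_error")
  }
  comp <- mixture$components
  dens <- vapply(seq_len(nrow(comp)), function(k) {
    comp$weight[k] * stats::dnorm(events$dwell_s, comp$mean_s[k],
                                  pmax(comp$sd_s[k], 1e-300))
  }, numeric(nrow(events)))
  dens <- matrix(dens, nrow = nrow(events))
  # ties break to the smaller component: max.col with ties.method "first"
  species <- if (nrow(events)) max.col(dens, ties.method = "first")
             else integer(0)
  cls <- ifelse(species >= 5, "o", as.character(species))
  out <- dplyr::mutate(events, species = species, species_class = cls)
  classes <- c(as.character(1:4), "o")
  if (nrow(events)) {
    resp <- dens / pmax(rowSums(dens), 1e-300)
    comp_units <- colSums(resp) * seq_len(nrow(comp))
    comp_cls <- ifelse(seq_len(nrow(comp)) >= 5, "o",
                       as.character(seq_len(nrow(comp))))
    fr <- vapply(classes, function(cc) {
      sum(comp_units[comp_cls == cc]) / sum(comp_units)
    }, 0)
  } else {
    fr <- stats::setNames(c(1, 0, 0, 0, 0), classes)
  }
  attr(out, "fractions") <- fr
  class(out) <- unique(c("dwell_set", class(out)))
  out
}
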