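#' Configure a height-spectroscopy diffusion simulation
#'
#' Defines a periodic square membrane patch carrying one or more diffusing
#' species (disk-shaped particles), a fixed tip detection disk at the
#' centre, a Gaussian baseline noise model and a z-feedback surrogate.
#' Particles propagate by 2D Brownian steps at the sampling interval; a
#' particle is detected when its centre is within `w/2` of the tip. The
#' ideal height at each sample is the maximum event height over detected
#' particles (the tip reports topography, not occupancy counts); the ideal
#' signal is low-pass filtered by the feedback surrogate and Gaussian
#' noise is added last.
#'
#' @param species A tibble from [species_geometry()], one row per species.
#' @param density_um2 Surface density per species, um^-2.
#' @param d_um2s Diffusion coefficient per species, um^2 s^-1.
#' @param height_nm Event height per species, nm (~2 nm for membrane-bound
#'   annexin-V).
#' @param duration_s Trace duration, s.
#' @param sampling_rate Sampling rate, Hz (default 625 kHz).
#' @param box_side_um Side of the periodic box, um. Defaults to at least
#'   ten detection widths, enlarged at low densities so the box holds at
#'   least one particle at unit density.
#' @param noise A [noise_model()].
#' @param feedback A [feedback_model()]; its sampling rate is overridden
#'   to match `sampling_rate`.
#' @param seed Optional RNG seed for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(species = species_geometry(),
                       density_um2 = 1.0,
                       d_um2s = 0.8,
                       height_nm = 2.0,
                       duration_s = 1,
                       sampling_rate = 625e3,
                       box_side_um = NULL,
                       noise = noise_model(),
                       feedback = feedback_model(),
                       seed = NULL) {
  stopifnot_positive(duration_s, "duration_s")
  stopifnot_positive(sampling_rate, "sampling_rate")
  n_sp <- nrow(species)
  density_um2 <- rep_len(density_um2, n_sp)
  d_um2s <- rep_len(d_um2s, n_sp)
  height_nm <- rep_len(height_nm, n_sp)
  stopifnot_nonneg(density_um2, "density_um2")
  stopifnot_nonneg(d_um2s, "d_um2s")
  w_um <- nm_to_um(max(species$w_nm))
  if (is.null(box_side_um)) {
    ctot <- sum(density_um2)
    box_side_um <- max(10 * w_um,
                       min(1, sqrt(32 / max(ctot, 1e-9))),
                       if (ctot > 0) sqrt(1 / ctot) else 0)
  }
  stopifnot_positive(box_side_um, "box_side_um")
  if (box_side_um < 10 * w_um) {
    rlang::abort("`box_side_um` must be at least 10 detection widths.",
                 class = "heightspec_config_error")
  }
  fb <- feedback_model(feedback$tau_fb_s, sampling_rate)
  structure(list(species = species, density_um2 = density_um2,
                 d_um2s = d_um2s, height_nm = height_nm,
                 duration_s = duration_s, sampling_rate = sampling_rate,
                 box_side_um = box_side_um, noise = noise, feedback = fb,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a height-spectroscopy trace of diffusing particles
#'
#' Runs the Brownian-dynamics measurement model defined by [sim_config()]
#' and returns the noisy, feedback-filtered height/time trace together
#' with the ground-truth occupancy intervals of each species.
#'
#' @param config A [sim_config()].
#' @param store_trajectories Keep per-particle trajectories (memory heavy;
#'   intended for short validation runs feeding [occupancy_oracle()]).
#' @param init_positions Optional list (one matrix per species, rows =
#'   particles, columns = x/y in um) overriding the uniform random start.
#' @param chunk_samples Internal chunk length for memory-bounded runs.
#' @return An [new_afm_trace()] with attributes `ground_truth` (tibble of
#'   occupancy intervals: `start_idx`, `end_idx`, `start_s`, `end_s`,
#'   `species`), `occupied_fraction` (ground-truth time fraction any
#'   particle is under the tip), `config`, and optionally `trajectories`.
#' @export
simulate_diffusion_trace <- function(config,
                                     store_trajectories = FALSE,
                                     init_positions = NULL,
                                     chunk_samples = 1e6) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_total <- round(config$duration_s * config$sampling_rate)
  dt <- 1 / config$sampling_rate
  box <- config$box_side_um
  tip <- c(box / 2, box / 2)
  n_sp <- nrow(config$species)
  n_part <- round(config$density_um2 * box^2)
  r_det_um <- nm_to_um(config$species$w_nm) / 2
  step_sd <- sqrt(2 * config$d_um2s * dt)

  pos <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    if (!is.null(init_positions) && length(init_positions) >= i &&
        !is.null(init_positions[[i]])) {
      pos[[i]] <- init_positions[[i]]
      n_part[i] <- nrow(pos[[i]])
    } else if (n_part[i] > 0) {
      pos[[i]] <- matrix(stats::runif(2 * n_part[i], 0, box), ncol = 2)
    }
  }

  heights <- numeric(n_total)
  occupied <- vector("list", n_sp)
  for (i in seq_len(n_sp)) occupied[[i]] <- logical(n_total)
  traj <- if (store_trajectories) {
    lapply(seq_len(n_sp), function(i)
      lapply(seq_len(n_part[i]), function(j) matrix(0, n_total, 2)))
  }

  filt_state <- 0
  done <- 0
  while (done < n_total) {
    m <- min(chunk_samples, n_total - done)
    idx <- done + seq_len(m)
    ideal <- numeric(m)
    for (i in seq_len(n_sp)) {
      if (n_part[i] == 0) next
      occ_i <- logical(m)
      for (j in seq_len(n_part[i])) {
        if (step_sd[i] > 0) {
          x <- pos[[i]][j, 1] + cumsum(stats::rnorm(m, 0, step_sd[i]))
          y <- pos[[i]][j, 2] + cumsum(stats::rnorm(m, 0, step_sd[i]))
          x <- x %% box
          y <- y %% box
          pos[[i]][j, ] <- c(x[m], y[m])
        } else {
          x <- rep(pos[[i]][j, 1], m)
          y <- rep(pos[[i]][j, 2], m)
        }
        if (store_trajectories) traj[[i]][[j]][idx, ] <- cbind(x, y)
        dx <- x - tip[1]; dx <- dx - box * round(dx / box)
        dy <- y - tip[2]; dy <- dy - box * round(dy / box)
        occ_i <- occ_i | (dx * dx + dy * dy < r_det_um[i]^2)
      }
      occupied[[i]][idx] <- occ_i
      ideal <- pmax(ideal, config$height_nm[i] * occ_i)
    }
    filt <- apply_feedback(ideal, config$feedback, init = filt_state)
    filt_state <- filt[m]
    heights[idx] <- filt + stats::rnorm(m, 0, config$noise$sigma_nm)
    done <- done + m
  }

  gt <- dplyr::bind_rows(lapply(seq_len(n_sp), function(i) {
    runs_to_intervals(occupied[[i]], config$sampling_rate, species = i)
  }))
  any_occ_frac <- if (n_sp == 1) mean(occupied[[1]]) else {
    any_occ <- Reduce(`|`, occupied)
    mean(any_occ)
  }
  out <- new_afm_trace(heights, config$sampling_rate,
                       ground_truth = gt,
                       occupied_fraction = any_occ_frac,
                       config = config, seed = config$seed)
  if (store_trajectories) attr(out, "trajectories") <- traj
  out
}

# rle of a logical occupancy vector -> interval tibble
runs_to_intervals <- function(occ, sampling_rate, species = 1L) {
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start_idx = starts[keep], end_idx = ends[keep],
    start_s = (starts[keep] - 1) / sampling_rate,
    end_s = ends[keep] / sampling_rate,
    species = as.integer(species)
  )
}

#' Exact occupancy intervals from stored trajectories
#'
#' Brute-force ground-truth reference: re-checks, frame by frame, whether
#' any particle centre lies within `w/2` of the tip (minimum-image
#' distance on the periodic box) and returns the resulting intervals.
#' Used to validate [simulate_diffusion_trace()] bookkeeping and
#' [detect_events()] on noiseless traces.
#'
#' @param trajectories A single n-by-2 matrix (um) or a list of such
#'   matrices, one per particle, all of equal length.
#' @param tip_um Tip position `c(x, y)`, um.
#' @param w_nm Effective detection width, nm.
#' @param box_side_um Periodic box side, um (use `Inf` for an open plane).
#' @param sampling_rate Sampling rate, Hz.
#' @return Tibble of occupancy intervals with attribute
#'   `occupied_fraction`.
#' @export
occupancy_oracle <- function(trajectories, tip_um, w_nm, box_side_um,
                             sampling_rate) {
  if (is.matrix(trajectories)) trajectories <- list(trajectories)
  if (length(trajectories) == 0) {
    out <- runs_to_intervals(logical(0), sampling_rate)
    attr(out, "occupied_fraction") <- NaN
    return(out)
  }
  lens <- vapply(trajectories, nrow, 0L)
  if (length(unique(lens)) != 1) {
    rlang::abort("Trajectories have mismatched lengths.",
                 class = "heightspec_config_error")
  }
  r2 <- (nm_to_um(w_nm) / 2)^2
  occ <- logical(lens[1])
  for (tr in trajectories) {
    dx <- tr[, 1] - tip_um[1]
    dy <- tr[, 2] - tip_um[2]
    if (is.finite(box_side_um)) {
      dx <- dx - box_side_um * round(dx / box_side_um)
      dy <- dy - box_side_um * round(dy / box_side_um)
    }
    occ <- occ | (dx * dx + dy * dy < r2)
  }
  out <- runs_to_intervals(occ, sampling_rate)
  attr(out, "occupied_fraction") <- mean(occ)
  out
}
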