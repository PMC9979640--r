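# Synthetic experiment generator. Emulates time-lapse pH-sensing scaffold
# data: 100-200 cells and a comparable number of fixed probes in a 500 um
# square field, 36 frames at 10 min spacing, heavy-tailed ground-truth
# fluxes spanning ~3 orders of magnitude, Gaussian pH noise at the probes.

place_points_min_sep <- function(n, L, min_sep, max_tries = 4000L) {
  xy <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    cand <- stats::runif(2, 0, L)
    ok <- placed == 0L ||
      min((xy[seq_len(placed), 1] - cand[1])^2 +
          (xy[seq_len(placed), 2] - cand[2])^2) >= min_sep^2
    if (ok) {
      placed <- placed + 1L
      xy[placed, ] <- cand
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        feasible <- floor(0.55 * L^2 / (pi * (min_sep / 2)^2))
        stop(sprintf(
          "could not place %d points with %g um separation in a %g um square (placed %d; feasible maximum is roughly %d)",
          n, min_sep, L, placed, feasible))
      }
    }
  }
  xy
}

draw_scenario_means <- function(scenario, n_cells, flux_scale, hub_factor,
                                hub_fraction, dipole_flux, dipole_fraction) {
  out <- list()
  if (scenario %in% c("hubs", "crossover")) {
    n_hub <- max(1L, round(hub_fraction * n_cells))
    hubs <- sample.int(n_cells, n_hub)
    m <- -abs(stats::rnorm(n_cells, 0, flux_scale))  # importing background
    m[hubs] <- hub_factor * flux_scale * abs(1 + 0.1 * stats::rnorm(n_hub))
    out$hub_means <- m
    out$hub_ids <- hubs
  }
  if (scenario %in% c("dipoles", "crossover")) {
    # sparse phase: a few strong donor-acceptor pairs over a weak background
    m <- stats::rnorm(n_cells, 0, 0.1 * flux_scale)
    n_pair <- floor(n_cells / 2)
    n_strong <- max(1L, round(dipole_fraction * n_pair))
    strong <- sort(sample.int(n_pair, n_strong))
    amp <- dipole_flux * abs(1 + 0.1 * stats::rnorm(n_strong))
    m[2 * strong - 1] <- amp
    m[2 * strong] <- -amp
    out$dipole_means <- m
    out$strong_pairs <- strong
  }
  out
}

#' Generate a synthetic pH-landscape experiment
#'
#' Produces a fully specified synthetic experiment: cell layouts (uniform
#' placement with a 10 um minimum separation, then a small reflected random
#' walk per frame), fixed probe positions, ground-truth per-cell fluxes
#' with one of four statistical structures, and probe pH read-outs equal to
#' the forward-model prediction plus Gaussian noise of standard deviation
#' `noise_sigma`. Cells in the `"dipoles"` scenario are laid out in close
#' donor-acceptor pairs; `"hubs"` plants a small fraction of cells at
#' `hub_factor` times the typical flux magnitude; `"crossover"` starts in
#' the hub regime and relaxes linearly into the dipole regime over the
#' course of the experiment. Temporal evolution follows an AR(1) process
#' around the scenario means so fluxes vary smoothly between frames.
#'
#' Probes whose noiseless predicted concentration would be non-positive or
#' whose pH would leave the range 3-11 (inside the near-field breakdown of the
#' point-source idealization) are re-placed during generation.
#'
#' @param scenario One of `"uniform"`, `"dipoles"`, `"hubs"`, `"crossover"`.
#' @param n_cells,n_probes,n_frames Problem size; defaults emulate the
#'   experimental regime (150 cells, 150 probes, 36 frames at 10 min).
#' @param noise_sigma Probe pH noise standard deviation (pH units).
#' @param seed Integer seed; the same seed reproduces all tables exactly.
#' @param params [physical_params()]; if `background_pH` is `NA` the
#'   generator uses pH 6.8 (mid-range of an acidifying culture medium).
#' @param flux_scale Typical flux magnitude (mmol/gdw/h). Default 1.
#' @param hub_factor,hub_fraction Hub magnitude multiplier and fraction of
#'   hub cells for the hub-dominated scenarios.
#' @param dipole_flux Dipole pair magnitude (mmol/gdw/h). Default 10.
#' @param dipole_fraction Fraction of cell pairs carrying the strong
#'   dipole flux in the sparse phase (the rest are weak background), so
#'   dipole motifs are isolated rather than frame-spanning. Default 0.15.
#' @param ar_rho AR(1) autocorrelation of per-cell fluxes across frames.
#' @param frame_dt_min Frame spacing in minutes.
#' @param cell_step_sd_um Per-frame cell displacement standard deviation.
#' @param flux_floor Minimum absolute flux (mmol/gdw/h); draws below it are
#'   pushed to the floor with their sign kept, so magnitudes span from the
#'   floor to the hubs (~3 orders of magnitude).
#' @return An object of class `synthetic_experiment`: list with `cells`,
#'   `probes` (both long data frames over frames; probes include the
#'   noiseless `pH_true`), `truth` (frame_index, time_min, cell_id,
#'   u_true_mmol_gdw_h), `params`, `noise_sigma`, `scenario`, `seed`.
#' @examples
#' ex <- generate_experiment("uniform", n_cells = 10, n_probes = 12,
#'                           n_frames = 2, seed = 1)
#' head(ex$truth)
#' @export
generate_experiment <- function(scenario = c("uniform", "dipoles", "hubs", "crossover"),
                                n_cells = 150L, n_probes = 150L, n_frames = 36L,
                                noise_sigma = 0.02, seed = 1L,
                                params = physical_params(),
                                flux_scale = 1, hub_factor = 100, hub_fraction = 0.05,
                                dipole_flux = 10, dipole_fraction = 0.15,
                                ar_rho = 0.95,
                                frame_dt_min = 10, cell_step_sd_um = 3,
                                flux_floor = 0.01) {
  scenario <- match.arg(scenario)
  stopifnot(n_cells >= 1, n_probes >= 1, n_frames >= 1, noise_sigma >= 0)
  if (is.na(params$background_pH)) params$background_pH <- 6.8
  set.seed(seed)
  L <- params$frame_size_um
  c0 <- 10^(-params$background_pH)

  # cell layout (dipole/crossover scenarios place pair partners adjacently)
  if (scenario %in% c("dipoles", "crossover")) {
    n_pair <- floor(n_cells / 2)
    anchors <- place_points_min_sep(n_pair + (n_cells - 2 * n_pair), L, 3 * 10)
    xy <- matrix(NA_real_, n_cells, 2)
    for (p in seq_len(n_pair)) {
      a <- anchors[p, ]
      th <- stats::runif(1, 0, 2 * pi)
      sep <- stats::runif(1, 15, 25)
      b <- a + sep * c(cos(th), sin(th))
      b <- pmin(pmax(b, 0), L)
      xy[2 * p - 1, ] <- a
      xy[2 * p, ] <- b
    }
    if (n_cells > 2 * n_pair) xy[n_cells, ] <- anchors[n_pair + 1L, ]
  } else {
    xy <- place_points_min_sep(n_cells, L, 10)
  }
  cell_ids <- sprintf("c%03d", seq_len(n_cells))

  # scenario means and AR(1) fluctuations
  sm <- draw_scenario_means(scenario, n_cells, flux_scale, hub_factor,
                            hub_fraction, dipole_flux, dipole_fraction)
  mean_at <- function(t) {
    switch(scenario,
      uniform = rep(0, n_cells),
      hubs = sm$hub_means,
      dipoles = sm$dipole_means,
      crossover = {
        w <- if (n_frames == 1L) 1 else 1 - (t - 1) / (n_frames - 1)
        w * sm$hub_means + (1 - w) * sm$dipole_means
      })
  }
  fluct_sd <- rep(flux_scale, n_cells)
  if (scenario %in% c("hubs", "crossover")) {
    fluct_sd[sm$hub_ids] <- 0.05 * abs(sm$hub_means[sm$hub_ids])
  }
  eps <- matrix(NA_real_, n_frames, n_cells)
  eps[1, ] <- stats::rnorm(n_cells, 0, fluct_sd)
  if (n_frames > 1) {
    for (t in 2:n_frames) {
      eps[t, ] <- ar_rho * eps[t - 1, ] +
        sqrt(1 - ar_rho^2) * stats::rnorm(n_cells, 0, fluct_sd)
    }
  }
  u_true <- matrix(NA_real_, n_frames, n_cells)
  for (t in seq_len(n_frames)) {
    u <- mean_at(t) + eps[t, ]
    small <- abs(u) < flux_floor
    u[small] <- ifelse(u[small] >= 0, flux_floor, -flux_floor)
    u_true[t, ] <- u
  }

  # cell trajectories: reflected random walk
  pos <- vector("list", n_frames)
  pos[[1]] <- xy
  if (n_frames > 1) {
    for (t in 2:n_frames) {
      step <- matrix(stats::rnorm(2 * n_cells, 0, cell_step_sd_um), n_cells, 2)
      p <- pos[[t - 1]] + step
      p <- abs(p)                       # reflect at 0
      p <- L - abs(L - p)               # reflect at L
      pos[[t]] <- p
    }
  }

  # probe positions: fixed over time, >= clamp distance from frame-1 cells,
  # re-placed if the noiseless field is unphysical in any frame
  probe_xy <- matrix(NA_real_, n_probes, 2)
  for (j in seq_len(n_probes)) probe_xy[j, ] <- stats::runif(2, 0, L)
  u_native <- flux_report_to_native(u_true, params)

  field_at_probes <- function(pxy) {
    sapply(seq_len(n_frames), function(t) {
      G <- build_distance_matrix(
        data.frame(cell_id = cell_ids, x_um = pos[[t]][, 1], y_um = pos[[t]][, 2]),
        data.frame(x_um = pxy[, 1, drop = TRUE], y_um = pxy[, 2, drop = TRUE]),
        params)
      as.numeric(c0 + G %*% c(0, u_native[t, ]))
    })
  }
  probe_ok <- function(cvals) all(cvals > 0) && all(-log10(cvals) >= 3) &&
    all(-log10(cvals) <= 11)
  cmat <- field_at_probes(probe_xy)   # n_probes x n_frames
  for (j in seq_len(n_probes)) {
    tries <- 0L
    while (TRUE) {
      near <- min((pos[[1]][, 1] - probe_xy[j, 1])^2 +
                  (pos[[1]][, 2] - probe_xy[j, 2])^2) < params$min_distance_um^2
      if (!near && probe_ok(cmat[j, ])) break
      tries <- tries + 1L
      if (tries > 500L) stop("could not place probe in a physical region of the field")
      probe_xy[j, ] <- stats::runif(2, 0, L)
      cmat[j, ] <- field_at_probes(probe_xy[j, , drop = FALSE])
    }
  }

  probe_ids <- sprintf("p%03d", seq_len(n_probes))
  sigma_rec <- max(noise_sigma, 1e-3)  # recorded probe error, must be > 0
  times <- (seq_len(n_frames) - 1) * frame_dt_min
  noise <- matrix(stats::rnorm(n_probes * n_frames, 0, noise_sigma),
                  n_probes, n_frames)

  cells_df <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    data.frame(frame_index = t, time_min = times[t], cell_id = cell_ids,
               x_um = pos[[t]][, 1], y_um = pos[[t]][, 2],
               cell_type = sample(c("tumor", "fibroblast"), n_cells, replace = TRUE))
  }))
  probes_df <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    pH_true <- -log10(cmat[, t])
    data.frame(frame_index = t, time_min = times[t], probe_id = probe_ids,
               x_um = probe_xy[, 1], y_um = probe_xy[, 2],
               pH = pH_true + noise[, t], sigma = sigma_rec, pH_true = pH_true)
  }))
  truth_df <- do.call(rbind, lapply(seq_len(n_frames), function(t) {
    data.frame(frame_index = t, time_min = times[t], cell_id = cell_ids,
               u_true_mmol_gdw_h = u_true[t, ])
  }))
  rownames(cells_df) <- rownames(probes_df) <- rownames(truth_df) <- NULL

  structure(
    list(cells = cells_df, probes = probes_df, truth = truth_df,
         boundary_truth = data.frame(frame_index = seq_len(n_frames),
                                     U_true_mmol_gdw_h = 0),
         params = params, noise_sigma = noise_sigma, scenario = scenario,
         seed = seed),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic pH-landscape experiment ('%s' scenario, seed %d)\n",
              x$scenario, x$seed))
  cat(sprintf("  %d cells, %d probes, %d frames; probe noise sigma = %g pH\n",
              length(unique(x$cells$cell_id)), length(unique(x$probes$probe_id)),
              max(x$cells$frame_index), x$noise_sigma))
  invisible(x)
}

#' Bulk pH / bulk efflux series consistent with a synthetic experiment
#'
#' The bulk efflux at frame t is the ground-truth mean single-cell flux
#' (plus optional observation noise); the paired bulk pH trace is obtained
#' by integrating the total cellular proton efflux into the stated medium
#' volume starting from the background concentration.
#'
#' @param experiment A [generate_experiment()] result.
#' @param obs_noise Standard deviation (mmol/gdw/h) of observation noise
#'   added to the bulk efflux read-out.
#' @return Data frame (class `bulk_series`) with `time_min`, `bulk_pH`,
#'   `bulk_concentration` (mol/L) and `bulk_u_mmol_gdw_h`.
#' @export
make_bulk_series <- function(experiment, obs_noise = 0) {
  stopifnot(inherits(experiment, "synthetic_experiment"), obs_noise >= 0)
  params <- experiment$params
  truth <- experiment$truth
  frames <- sort(unique(truth$frame_index))
  times <- vapply(frames, function(t) truth$time_min[truth$frame_index == t][1], 0)
  u_mean <- vapply(frames, function(t) mean(truth$u_true_mmol_gdw_h[truth$frame_index == t]), 0)
  u_tot_native <- vapply(frames, function(t) {
    sum(flux_report_to_native(truth$u_true_mmol_gdw_h[truth$frame_index == t], params))
  }, 0)
  c0 <- 10^(-if (is.na(params$background_pH)) 6.8 else params$background_pH)
  conc <- numeric(length(frames))
  conc[1] <- c0
  if (length(frames) > 1) {
    for (k in 2:length(frames)) {
      dt_s <- (times[k] - times[k - 1]) * 60
      conc[k] <- conc[k - 1] + u_tot_native[k - 1] * dt_s / params$medium_volume_L
    }
  }
  if (any(conc <= 0)) stop("bulk concentration became non-positive; medium volume too small")
  ub <- u_mean + if (obs_noise > 0) stats::rnorm(length(frames), 0, obs_noise) else 0
  out <- data.frame(time_min = times, bulk_pH = -log10(conc),
                    bulk_concentration = conc, bulk_u_mmol_gdw_h = ub)
  class(out) <- c("bulk_series", "data.frame")
  out
}
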