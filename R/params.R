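# Unit conventions used throughout:
#   positions      micrometres (um), origin at the lower-left frame corner
#   diffusion D    um^2 / s
#   concentration  mol / L  (1 L = 1e15 um^3)
#   native flux    mol / s per cell
#   reported flux  mmol per gram dry weight per hour (mmol/gdw/h)

#' Volumetric conversion factor, cubic micrometres per litre
#' @keywords internal
UM3_PER_L <- 1e15

#' Physical parameters of the pH landscape model
#'
#' Bundles the physical constants of the stationary diffusion model: the
#' proton diffusion coefficient, the linear size of the observed square
#' frame, the average cell dry weight used to express fluxes in
#' mmol/gdw/h, the background (far-field) medium pH, and the
#' discretization of the frame-boundary source term.
#'
#' @param diffusion_um2_s Proton diffusion coefficient in um^2/s.
#'   Default 7e3, the standard aqueous value at the relevant scale.
#' @param frame_size_um Linear size L of the square observation frame (um).
#' @param cell_dry_weight_ng Average cell dry weight in ng, used to convert
#'   native fluxes (mol/s) to specific fluxes (mmol/gdw/h). Default 0.5.
#' @param background_pH Far-field medium pH fixing the background
#'   concentration c0. `NA` (default) means c0 is estimated per frame from
#'   the median probe pH.
#' @param medium_volume_L Volume of medium (L) over the observed culture,
#'   used only when relating bulk pH drift to total cellular efflux.
#' @param boundary_points Number of virtual point sources equally spaced on
#'   the frame perimeter that discretize the boundary flux term. Must be
#'   at least 4; default 64.
#' @param min_distance_um Minimum probe-cell distance (um); smaller
#'   distances are clamped to this value, encoding the finite cell radius
#'   below which the point-source idealization breaks down.
#' @return An object of class `physical_params` (a named list).
#' @examples
#' p <- physical_params()
#' p$diffusion_um2_s
#' @export
physical_params <- function(diffusion_um2_s = 7e3,
                            frame_size_um = 500,
                            cell_dry_weight_ng = 0.5,
                            background_pH = NA_real_,
                            medium_volume_L = 1e-4,
                            boundary_points = 64L,
                            min_distance_um = 5) {
  stopifnot(
    is.numeric(diffusion_um2_s), length(diffusion_um2_s) == 1L, diffusion_um2_s > 0,
    is.numeric(frame_size_um), length(frame_size_um) == 1L, frame_size_um > 0,
    is.numeric(cell_dry_weight_ng), length(cell_dry_weight_ng) == 1L, cell_dry_weight_ng > 0,
    is.numeric(medium_volume_L), medium_volume_L > 0,
    is.numeric(boundary_points), boundary_points >= 4,
    is.numeric(min_distance_um), min_distance_um >= 0
  )
  if (!is.na(background_pH) && (background_pH < 3 || background_pH > 11)) {
    stop("background_pH outside the plausible physical range [3, 11]")
  }
  structure(
    list(
      diffusion_um2_s = diffusion_um2_s,
      frame_size_um = frame_size_um,
      cell_dry_weight_ng = cell_dry_weight_ng,
      background_pH = background_pH,
      medium_volume_L = medium_volume_L,
      boundary_points = as.integer(boundary_points),
      min_distance_um = min_distance_um
    ),
    class = "physical_params"
  )
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical parameters of the pH landscape model\n")
  cat(sprintf("  D                : %g um^2/s\n", x$diffusion_um2_s))
  cat(sprintf("  frame size L     : %g um\n", x$frame_size_um))
  cat(sprintf("  cell dry weight  : %g ng\n", x$cell_dry_weight_ng))
  cat(sprintf("  background pH    : %s\n",
              if (is.na(x$background_pH)) "estimated per frame (median probe pH)"
              else format(x$background_pH)))
  cat(sprintf("  boundary sources : %d on the perimeter\n", x$boundary_points))
  cat(sprintf("  distance clamp   : %g um\n", x$min_distance_um))
  invisible(x)
}

#' Convert a native flux (mol/s) to a specific flux (mmol/gdw/h)
#'
#' Reported fluxes are expressed per gram of cell dry weight per hour so
#' that single-cell values are directly comparable with bulk metabolic
#' flux measurements. The conversion multiplies by 3.6e6
#' (mol/s to mmol/h) and divides by the dry weight in grams.
#'
#' @param u_native Numeric vector of fluxes in mol/s.
#' @param params A [physical_params()] object supplying the dry weight.
#' @return Fluxes in mmol/gdw/h.
#' @examples
#' convert_flux_units(1.389e-15, physical_params()) # ~ 10 mmol/gdw/h
#' @export
convert_flux_units <- function(u_native, params = physical_params()) {
  stopifnot(inherits(params, "physical_params"))
  dw_g <- params$cell_dry_weight_ng * 1e-9
  u_native * 3.6e6 / dw_g
}

#' Convert a specific flux (mmol/gdw/h) back to native units (mol/s)
#'
#' Inverse of [convert_flux_units()].
#' @inheritParams convert_flux_units
#' @param u_report Numeric vector of fluxes in mmol/gdw/h.
#' @return Fluxes in mol/s.
#' @export
flux_report_to_native <- function(u_report, params = physical_params()) {
  stopifnot(inherits(params, "physical_params"))
  dw_g <- params$cell_dry_weight_ng * 1e-9
  u_report * dw_g / 3.6e6
}

#' Inference hyperparameters
#'
#' Regularization weights and sampler settings for the flux inference.
#' `lambda1` weighs the per-frame Gaussian (Tikhonov) prior on the
#' single-cell fluxes, `lambda2` the temporal-smoothness penalty on
#' tracked cells across consecutive frames, and `lambda3` the soft
#' constraint tying the per-frame mean flux to the measured bulk efflux.
#' Any of the three left `NA` is resolved at fit time: `lambda1` by
#' generalized cross-validation on the linearized per-frame problem,
#' `lambda2 = lambda1 / 10`, and `lambda3` so the bulk term contributes
#' about 10% of the initial data misfit (0 when no bulk series is given).
#'
#' @param lambda1,lambda2,lambda3 Non-negative weights, or `NA` for the
#'   data-driven defaults above.
#' @param temp_initial,cooling,steps_per_temp Simulated-annealing schedule:
#'   geometric cooling from `temp_initial` down to 1 by factor `cooling`,
#'   with `steps_per_temp` full-vector Metropolis proposals per level.
#' @param n_samples Posterior samples kept after burn-in.
#' @param burn_in Burn-in steps during which the proposal scale adapts;
#'   adaptation is frozen afterwards so the sampling phase satisfies
#'   detailed balance.
#' @param max_displacement_um Gate for cell tracking across consecutive
#'   frames (um per frame interval).
#' @param bulk_statistic Whether the bulk constraint compares the bulk
#'   efflux to the `"mean"` (default) or the `"sum"` of per-cell fluxes.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(lambda1 = NA_real_, lambda2 = NA_real_, lambda3 = NA_real_,
                         temp_initial = 100, cooling = 0.95, steps_per_temp = 200L,
                         n_samples = 2000L, burn_in = 1000L,
                         max_displacement_um = 30,
                         bulk_statistic = c("mean", "sum")) {
  bulk_statistic <- match.arg(bulk_statistic)
  for (nm in c("lambda1", "lambda2", "lambda3")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop(nm, " must be >= 0")
  }
  stopifnot(temp_initial >= 1, cooling > 0, cooling < 1,
            steps_per_temp >= 1, n_samples >= 1, burn_in >= 0,
            max_displacement_um > 0)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         temp_initial = temp_initial, cooling = cooling,
         steps_per_temp = as.integer(steps_per_temp),
         n_samples = as.integer(n_samples), burn_in = as.integer(burn_in),
         max_displacement_um = max_displacement_um,
         bulk_statistic = bulk_statistic),
    class = "hyper_params"
  )
}

#' @export
print.hyper_params <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "auto" else format(v)
  cat("Inference hyperparameters\n")
  cat(sprintf("  lambda1 (flux prior)       : %s\n", fmt(x$lambda1)))
  cat(sprintf("  lambda2 (temporal smooth)  : %s\n", fmt(x$lambda2)))
  cat(sprintf("  lambda3 (bulk consistency) : %s\n", fmt(x$lambda3)))
  cat(sprintf("  annealing                  : T %g -> 1, factor %g, %d steps/level\n",
              x$temp_initial, x$cooling, x$steps_per_temp))
  cat(sprintf("  posterior samples          : %d (+%d burn-in)\n",
              x$n_samples, x$burn_in))
  invisible(x)
}
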