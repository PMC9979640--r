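# Forward model: stationary proton concentration field generated by
# point-like cellular sources plus a frame-boundary flux. Each cell is the
# monopole term of the multipole expansion of a Laplace solution,
#   c(r) = c0 + sum_i u_i / (4 pi D |r - r_i|) + boundary term,
# with the boundary flux U spread over virtual sources on the perimeter.

#' Monopole kernel matrix between probes and cells (plus boundary column)
#'
#' Builds the M x (N + 1) kernel matrix G such that `c = c0 + G %*% u`
#' gives the predicted proton concentration (mol/L) at the M probe
#' positions for native fluxes `u` in mol/s. Column 1 is the boundary
#' kernel: the average of monopole kernels over `params$boundary_points`
#' virtual sources equally spaced on the frame perimeter, carrying the
#' total boundary flux U. Columns 2..(N+1) are the per-cell monopole
#' kernels 1e15 / (4 pi D d), with d the probe-cell distance in um
#' clamped from below at `params$min_distance_um` (finite cell size).
#'
#' @param cells Data frame with columns `x_um`, `y_um` and optionally
#'   `cell_id` (one frame). May have zero rows, in which case the matrix
#'   has only the boundary column.
#' @param probes Data frame with columns `x_um`, `y_um` and optionally
#'   `probe_id` (one frame).
#' @param params A [physical_params()] object.
#' @return Numeric matrix, M x (N + 1), units L^-1 s (concentration per
#'   unit native flux); column names `"boundary"` then cell ids.
#' @examples
#' p <- physical_params()
#' G <- build_distance_matrix(
#'   data.frame(cell_id = "c1", x_um = 0, y_um = 0),
#'   data.frame(probe_id = "p1", x_um = 100, y_um = 0), p
#' )
#' G[1, "c1"] # 1e15 / (4 * pi * 7000 * 100) = 1.1368e8
#' @export
build_distance_matrix <- function(cells, probes, params = physical_params()) {
  stopifnot(inherits(params, "physical_params"))
  stopifnot(is.data.frame(probes), all(c("x_um", "y_um") %in% names(probes)))
  if (!is.data.frame(cells)) stop("`cells` must be a data frame")
  n_cells <- nrow(cells)
  m <- nrow(probes)
  if (m == 0L) stop("probe table is empty")
  px <- probes$x_um
  py <- probes$y_um

  kfac <- UM3_PER_L / (4 * pi * params$diffusion_um2_s)
  dmin <- params$min_distance_um

  # boundary column: mean monopole kernel over perimeter points
  nb <- params$boundary_points
  L <- params$frame_size_um
  per <- seq(0, 4 * L, length.out = nb + 1L)[-(nb + 1L)]
  bx <- numeric(nb); by <- numeric(nb)
  s1 <- per < L; s2 <- per >= L & per < 2 * L
  s3 <- per >= 2 * L & per < 3 * L; s4 <- per >= 3 * L
  bx[s1] <- per[s1];           by[s1] <- 0
  bx[s2] <- L;                 by[s2] <- per[s2] - L
  bx[s3] <- 3 * L - per[s3];   by[s3] <- L
  bx[s4] <- 0;                 by[s4] <- 4 * L - per[s4]
  db <- sqrt(outer(px, bx, "-")^2 + outer(py, by, "-")^2)
  db <- pmax(db, dmin)
  g_boundary <- rowMeans(kfac / db)

  if (n_cells > 0L) {
    stopifnot(all(c("x_um", "y_um") %in% names(cells)))
    d <- sqrt(outer(px, cells$x_um, "-")^2 + outer(py, cells$y_um, "-")^2)
    zero <- which(d == 0, arr.ind = TRUE)
    if (nrow(zero) > 0L) {
      pid <- if ("probe_id" %in% names(probes)) probes$probe_id[zero[1, 1]] else zero[1, 1]
      cid <- if ("cell_id" %in% names(cells)) cells$cell_id[zero[1, 2]] else zero[1, 2]
      stop(sprintf("probe '%s' coincides with cell '%s' (zero distance)", pid, cid))
    }
    d <- pmax(d, dmin)
    G <- cbind(g_boundary, kfac / d)
    colnames(G) <- c("boundary",
                     if ("cell_id" %in% names(cells)) as.character(cells$cell_id)
                     else paste0("cell", seq_len(n_cells)))
  } else {
    G <- matrix(g_boundary, ncol = 1L, dimnames = list(NULL, "boundary"))
  }
  G
}

#' Predicted proton concentration at the probes
#'
#' Evaluates the linear forward model `c = c0 + G %*% u` for native
#' fluxes `u` (mol/s; element 1 is the boundary flux U). A non-positive
#' predicted concentration is physically impossible for the true field and
#' signals an unphysical flux configuration; it is flagged via the
#' `"unphysical"` attribute (the likelihood treats such configurations as
#' having -Inf log-probability).
#'
#' @param fluxes Numeric vector of native fluxes (mol/s), length
#'   `ncol(kernel)`, first element the boundary flux U.
#' @param kernel Kernel matrix from [build_distance_matrix()].
#' @param c0 Background concentration in mol/L (scalar).
#' @return Numeric vector of concentrations (mol/L) with attribute
#'   `unphysical` (logical).
#' @export
concentration_field <- function(fluxes, kernel, c0) {
  stopifnot(is.numeric(fluxes), is.matrix(kernel),
            length(fluxes) == ncol(kernel),
            is.numeric(c0), length(c0) == 1L, c0 > 0)
  if (!all(is.finite(fluxes))) stop("fluxes must be finite")
  cc <- as.numeric(c0 + kernel %*% fluxes)
  attr(cc, "unphysical") <- any(cc <= 0)
  cc
}

#' pH from proton concentration
#'
#' `pH = -log10(c)` with `c` in mol/L.
#'
#' @param concentration Numeric vector of concentrations (mol/L), all > 0.
#' @return pH vector.
#' @examples
#' predicted_pH(1e-7) # 7
#' @export
predicted_pH <- function(concentration) {
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("non-positive or non-finite concentration: unphysical field")
  }
  -log10(as.numeric(concentration))
}

#' Background concentration for a frame
#'
#' Returns the background proton concentration c0 (mol/L): either fixed by
#' `params$background_pH`, or estimated as the concentration corresponding
#' to the median probe pH of the frame.
#'
#' @param probe_pH Numeric vector of measured probe pH values for a frame.
#' @param params A [physical_params()] object.
#' @return Scalar concentration (mol/L).
#' @export
background_concentration <- function(probe_pH, params = physical_params()) {
  if (!is.na(params$background_pH)) return(10^(-params$background_pH))
  stopifnot(length(probe_pH) >= 1, all(is.finite(probe_pH)))
  10^(-stats::median(probe_pH))
}
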