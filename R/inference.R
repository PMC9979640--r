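# Flux inference: Tikhonov-regularized maximum likelihood on the monopole
# forward model. The posterior P(u) ~ exp(-chi2_tot(u)) is explored with a
# Gauss-Newton (ridge) warm start, Metropolis-Hastings sampling
# preconditioned by the warm-start covariance, and simulated annealing for
# the MAP. All fluxes are handled internally in reporting units
# (mmol/gdw/h); the kernel is rescaled accordingly.

LN10 <- log(10)

#' Prepare frames for inference
#'
#' Splits long cell/probe tables into per-frame blocks, builds the
#' monopole kernel of each frame (rescaled so that fluxes are in
#' mmol/gdw/h), fixes the per-frame background concentration c0, and runs
#' cell tracking for the temporal-smoothness penalty.
#'
#' @param cells,probes Long data frames over frames (see
#'   [read_cell_table()] for the column contract).
#' @param params A [physical_params()] object.
#' @param max_displacement_um Tracking gate passed to [track_cells()].
#' @return Object of class `frame_prep`: list with `frames` (per-frame
#'   blocks), `tracking`, `dim` (total coordinate count), `params`.
#' @export
prepare_frames <- function(cells, probes, params = physical_params(),
                           max_displacement_um = 30) {
  stopifnot(is.data.frame(cells), is.data.frame(probes))
  f_ids <- sort(unique(probes$frame_index))
  native_per_report <- flux_report_to_native(1, params)
  frames <- list()
  offset <- 0L
  for (fi in f_ids) {
    cf <- cells[cells$frame_index == fi, , drop = FALSE]
    pf <- probes[probes$frame_index == fi, , drop = FALSE]
    if (nrow(pf) == 0L) stop("frame ", fi, " has no probes")
    if (any(pf$sigma <= 0)) stop("frame ", fi, ": probe sigma must be > 0")
    G <- build_distance_matrix(cf, pf, params)
    c0 <- background_concentration(pf$pH, params)
    np1 <- ncol(G)
    frames[[length(frames) + 1L]] <- list(
      frame_index = fi,
      time_min = if (nrow(pf)) pf$time_min[1] else NA_real_,
      cell_ids = colnames(G)[-1L],
      probe_ids = if ("probe_id" %in% names(pf)) as.character(pf$probe_id)
                  else as.character(seq_len(nrow(pf))),
      A = G * native_per_report,   # report-unit design matrix
      c0 = c0,
      pH = pf$pH,
      sigma = pf$sigma,
      offset = offset,
      np1 = np1
    )
    offset <- offset + np1
  }
  ord <- order(vapply(frames, `[[`, 0, "time_min"))
  if (any(diff(ord) != 1)) frames <- frames[ord]
  offset <- 0L
  for (k in seq_along(frames)) {
    frames[[k]]$offset <- offset
    offset <- offset + frames[[k]]$np1
  }
  structure(
    list(frames = frames,
         tracking = track_cells(cells, max_displacement_um),
         dim = offset, params = params),
    class = "frame_prep"
  )
}

coord_labels <- function(prep) {
  unlist(lapply(prep$frames, function(f)
    paste0("f", f$frame_index, ":", c("boundary", f$cell_ids))))
}

# global coordinate indices of the temporal-smoothness pairs
tracking_pairs <- function(prep) {
  tr <- prep$tracking
  if (nrow(tr) == 0L) return(list(i1 = integer(), i2 = integer()))
  fidx <- vapply(prep$frames, `[[`, 0, "frame_index")
  i1 <- integer(); i2 <- integer()
  for (r in seq_len(nrow(tr))) {
    k <- match(tr$frame_from[r], fidx)
    if (is.na(k) || k >= length(prep$frames)) next
    f1 <- prep$frames[[k]]; f2 <- prep$frames[[k + 1]]
    j1 <- match(tr$id_from[r], f1$cell_ids)
    j2 <- match(tr$id_to[r], f2$cell_ids)
    if (is.na(j1) || is.na(j2)) next
    i1 <- c(i1, f1$offset + 1L + j1)
    i2 <- c(i2, f2$offset + 1L + j2)
  }
  list(i1 = i1, i2 = i2)
}

# closure evaluating chi2_tot(v) and assembling Gauss-Newton systems
make_objective <- function(prep, lambda1, lambda2, lambda3,
                           bulk = NULL, bulk_statistic = "mean") {
  frames <- prep$frames
  d <- prep$dim
  pairs <- if (lambda2 > 0) tracking_pairs(prep) else list(i1 = integer(), i2 = integer())
  ub <- NULL
  if (lambda3 > 0) {
    if (is.null(bulk)) {
      stop("lambda3 > 0 requires a bulk series; supply bulk data or set lambda3 = 0")
    }
    ub <- vapply(frames, function(f) {
      k <- which.min(abs(bulk$time_min - f$time_min))
      bulk$bulk_u_mmol_gdw_h[k]
    }, 0)
  }
  cell_idx <- lapply(frames, function(f) f$offset + 1L + seq_along(f$cell_ids))

  chi2 <- function(v) {
    tot <- 0
    for (k in seq_along(frames)) {
      f <- frames[[k]]
      vt <- v[f$offset + seq_len(f$np1)]
      cc <- f$c0 + as.numeric(f$A %*% vt)
      if (any(cc <= 0)) return(Inf)
      r <- (f$pH + log10(cc)) / f$sigma
      tot <- tot + sum(r * r)
      if (lambda1 > 0 && f$np1 > 1L) tot <- tot + lambda1 * sum(vt[-1L]^2)
    }
    if (lambda2 > 0 && length(pairs$i1)) {
      dv <- v[pairs$i2] - v[pairs$i1]
      tot <- tot + lambda2 * sum(dv * dv)
    }
    if (lambda3 > 0) {
      for (k in seq_along(frames)) {
        ci <- cell_idx[[k]]
        if (!length(ci)) next
        stat <- if (bulk_statistic == "mean") mean(v[ci]) else sum(v[ci])
        tot <- tot + lambda3 * (stat - ub[k])^2
      }
    }
    tot
  }

  # Gauss-Newton normal system at expansion point v0:
  # (B'B + lambda terms) v = B'(B v0 - r0) + lambda3 targets
  gn_system <- function(v0) {
    H <- matrix(0, d, d)
    g <- numeric(d)
    for (k in seq_along(frames)) {
      f <- frames[[k]]
      idx <- f$offset + seq_len(f$np1)
      vt <- v0[idx]
      cc <- f$c0 + as.numeric(f$A %*% vt)
      cc <- pmax(cc, 1e-3 * f$c0)   # keep linearization finite near zero
      B <- f$A / (f$sigma * cc * LN10)
      r0 <- (f$pH + log10(cc)) / f$sigma
      H[idx, idx] <- H[idx, idx] + crossprod(B)
      g[idx] <- g[idx] + as.numeric(crossprod(B, as.numeric(B %*% vt) - r0))
      if (lambda1 > 0 && f$np1 > 1L) {
        di <- idx[-1L]
        H[cbind(di, di)] <- H[cbind(di, di)] + lambda1
      }
    }
    if (lambda2 > 0 && length(pairs$i1)) {
      for (r in seq_along(pairs$i1)) {
        i <- pairs$i1[r]; j <- pairs$i2[r]
        H[i, i] <- H[i, i] + lambda2
        H[j, j] <- H[j, j] + lambda2
        H[i, j] <- H[i, j] - lambda2
        H[j, i] <- H[j, i] - lambda2
      }
    }
    if (lambda3 > 0) {
      for (k in seq_along(frames)) {
        ci <- cell_idx[[k]]
        if (!length(ci)) next
        w <- numeric(d)
        w[ci] <- if (bulk_statistic == "mean") 1 / length(ci) else 1
        H <- H + lambda3 * tcrossprod(w)
        g <- g + lambda3 * ub[k] * w
      }
    }
    list(H = H, g = g)
  }

  list(chi2 = chi2, gn_system = gn_system, dim = d, frames = frames,
       cell_idx = cell_idx, lambda1 = lambda1, lambda2 = lambda2,
       lambda3 = lambda3)
}

#' Per-frame cost function
#'
#' The data misfit of one frame plus the Tikhonov flux prior:
#' `sum_mu ((pH_mu - pHhat_mu(u)) / sigma_mu)^2 + lambda1 * sum_i u_i^2`,
#' where the sum of squares over fluxes runs over cells only (the boundary
#' flux U is unpenalized). Any non-positive predicted concentration makes
#' the cost `Inf`.
#'
#' @param u Flux vector in mmol/gdw/h, length `ncol(kernel)`, first
#'   element the boundary flux U.
#' @param probes Probe table for the frame (columns `pH`, `sigma`).
#' @param kernel Native kernel from [build_distance_matrix()].
#' @param params A [physical_params()] object.
#' @param c0 Background concentration (mol/L); default from
#'   [background_concentration()].
#' @param lambda1 Tikhonov weight, >= 0.
#' @return Scalar cost.
#' @export
frame_chi2 <- function(u, probes, kernel, params = physical_params(),
                       c0 = NULL, lambda1 = 0) {
  stopifnot(length(u) == ncol(kernel), all(probes$sigma > 0), lambda1 >= 0)
  if (is.null(c0)) c0 <- background_concentration(probes$pH, params)
  cc <- concentration_field(flux_report_to_native(u, params), kernel, c0)
  if (attr(cc, "unphysical")) return(Inf)
  r <- (probes$pH - predicted_pH(cc)) / probes$sigma
  sum(r * r) + if (length(u) > 1L) lambda1 * sum(u[-1L]^2) else 0
}

#' Total cost across frames
#'
#' Sum of the per-frame costs plus the temporal-smoothness penalty
#' (`lambda2`, applied to tracked cells across consecutive frames) and the
#' bulk-consistency penalty (`lambda3`, tying the per-frame mean flux to
#' the measured bulk efflux).
#'
#' @param u_frames List of per-frame flux vectors (mmol/gdw/h; first
#'   element of each is the boundary flux), in the frame order of `prep`.
#' @param prep A [prepare_frames()] object.
#' @param lambda1,lambda2,lambda3 Non-negative weights.
#' @param bulk Optional bulk series (data frame with `time_min`,
#'   `bulk_u_mmol_gdw_h`); required when `lambda3 > 0`.
#' @param bulk_statistic `"mean"` or `"sum"` (see [hyper_params()]).
#' @return Scalar total cost.
#' @export
total_chi2 <- function(u_frames, prep, lambda1 = 0, lambda2 = 0, lambda3 = 0,
                       bulk = NULL, bulk_statistic = "mean") {
  stopifnot(inherits(prep, "frame_prep"),
            length(u_frames) == length(prep$frames))
  obj <- make_objective(prep, lambda1, lambda2, lambda3, bulk, bulk_statistic)
  obj$chi2(unlist(u_frames, use.names = FALSE))
}

#' Generalized cross-validation choice of lambda1
#'
#' Evaluates the GCV score of the ridge problem obtained by linearizing
#' each frame's pH response at u = 0, summed over frames, on a log-spaced
#' grid, and returns the minimizing weight. Used as the data-driven
#' default for `lambda1`.
#'
#' @param prep A [prepare_frames()] object.
#' @param grid Candidate lambda values.
#' @return Scalar lambda1.
#' @export
choose_lambda1_gcv <- function(prep, grid = 10^seq(-4, 4, length.out = 33)) {
  rss <- matrix(0, length(grid), 1)
  df <- numeric(length(grid))
  m_tot <- 0
  for (f in prep$frames) {
    B <- f$A / (f$sigma * f$c0 * LN10)
    y <- (f$pH + log10(f$c0)) / f$sigma
    sv <- svd(B)
    uy <- crossprod(sv$u, y)
    m_tot <- m_tot + length(y)
    for (k in seq_along(grid)) {
      shrink <- sv$d^2 / (sv$d^2 + grid[k])
      fit <- sv$u %*% (shrink * uy)
      rss[k] <- rss[k] + sum((y - fit)^2)
      df[k] <- df[k] + sum(shrink)
    }
  }
  gcv <- (rss / m_tot) / (pmax(1 - df / m_tot, 1e-8))^2
  grid[which.min(gcv)]
}

#' Resolve NA hyperparameters from the data
#'
#' `lambda1` defaults to the GCV choice on the linearized problem,
#' `lambda2` to `lambda1 / 10`, and `lambda3` to the weight at which the
#' bulk term contributes about 10% of the initial (u = 0) data misfit,
#' or 0 when no bulk series is supplied.
#'
#' @param prep A [prepare_frames()] object.
#' @param hyper A [hyper_params()] object (possibly with NA lambdas).
#' @param bulk Optional bulk series.
#' @return `hyper` with all lambdas numeric.
#' @export
resolve_hyperparams <- function(prep, hyper = hyper_params(), bulk = NULL) {
  stopifnot(inherits(hyper, "hyper_params"))
  if (is.na(hyper$lambda1)) hyper$lambda1 <- choose_lambda1_gcv(prep)
  if (is.na(hyper$lambda2)) hyper$lambda2 <- hyper$lambda1 / 10
  if (is.na(hyper$lambda3)) {
    if (is.null(bulk)) {
      hyper$lambda3 <- 0
    } else {
      chi0 <- sum(vapply(prep$frames, function(f) {
        sum(((f$pH + log10(f$c0)) / f$sigma)^2)
      }, 0))
      ub <- vapply(prep$frames, function(f) {
        k <- which.min(abs(bulk$time_min - f$time_min))
        bulk$bulk_u_mmol_gdw_h[k]
      }, 0)
      denom <- sum(ub^2)
      hyper$lambda3 <- if (denom > 0) 0.1 * chi0 / denom else 0
    }
  }
  if (hyper$lambda3 > 0 && is.null(bulk)) {
    stop("lambda3 > 0 requires a bulk series; supply bulk data or set lambda3 = 0")
  }
  hyper
}

#' Gauss-Newton warm start (iterated linearized ridge solution)
#'
#' Linearizes the pH response around the current expansion point, solves
#' the resulting ridge-regression problem in closed form (all penalty
#' terms are exactly quadratic), and iterates to the fixed point with step
#' halving whenever the exact cost would increase.
#'
#' @param prep A [prepare_frames()] object.
#' @param hyper A [hyper_params()] object; NA lambdas are resolved via
#'   [resolve_hyperparams()].
#' @param bulk Optional bulk series.
#' @param v0 Starting point (default all-zero fluxes).
#' @param max_iter,tol Iteration controls.
#' @return List with `v` (stacked flux vector, mmol/gdw/h), `chi2`,
#'   `hyper` (resolved), `n_iter`.
#' @export
gaussian_warm_start <- function(prep, hyper = hyper_params(), bulk = NULL,
                                v0 = NULL, max_iter = 60L, tol = 1e-10) {
  stopifnot(inherits(prep, "frame_prep"))
  hyper <- resolve_hyperparams(prep, hyper, bulk)
  obj <- make_objective(prep, hyper$lambda1, hyper$lambda2, hyper$lambda3,
                        bulk, hyper$bulk_statistic)
  v <- if (is.null(v0)) numeric(prep$dim) else v0
  f_cur <- obj$chi2(v)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    sys <- obj$gn_system(v)
    R <- tryCatch(chol(sys$H), error = function(e) NULL)
    if (is.null(R)) {
      stop("singular normal matrix: the linearized problem is underdetermined; ",
           "set lambda1 > 0 (the Tikhonov regularizer prevents multicollinearity)")
    }
    v_new <- backsolve(R, backsolve(R, sys$g, transpose = TRUE))
    f_new <- obj$chi2(v_new)
    halvings <- 0L
    while ((!is.finite(f_new) || f_new > f_cur + 1e-12) && halvings < 40L) {
      v_new <- (v_new + v) / 2
      f_new <- obj$chi2(v_new)
      halvings <- halvings + 1L
    }
    if (!is.finite(f_new) || f_new > f_cur + 1e-12) break
    delta <- max(abs(v_new - v)) / (1 + max(abs(v_new)))
    v <- v_new
    f_cur <- f_new
    if (delta < tol) break
  }
  list(v = v, chi2 = f_cur, hyper = hyper, n_iter = n_iter, objective = obj)
}

# ---- Metropolis-Hastings engine ------------------------------------------

# fn: target cost (sampled density ~ exp(-fn/temperature))
# prop_chol: upper Cholesky factor R of a precision-like matrix; proposal
#   steps are scale * backsolve(R, z) so their covariance is scale^2 R^-1 R^-T
mh_engine <- function(fn, v0, n_steps, scale = 0.1, prop_chol = NULL,
                      temperature = 1, record = FALSE, adapt = FALSE,
                      target_acc = 0.3, adapt_block = 50L) {
  v <- v0
  d <- length(v)
  f_cur <- fn(v)
  best_v <- v
  best_f <- f_cur
  n_acc <- 0L
  block_acc <- 0L
  samples <- if (record) matrix(NA_real_, n_steps, d) else NULL
  for (s in seq_len(n_steps)) {
    z <- stats::rnorm(d)
    dv <- if (is.null(prop_chol)) scale * z else scale * backsolve(prop_chol, z)
    v_prop <- v + dv
    f_prop <- fn(v_prop)
    if (is.finite(f_prop) &&
        log(stats::runif(1)) < -(f_prop - f_cur) / temperature) {
      v <- v_prop
      f_cur <- f_prop
      n_acc <- n_acc + 1L
      block_acc <- block_acc + 1L
      if (f_cur < best_f) {
        best_f <- f_cur
        best_v <- v
      }
    }
    if (record) samples[s, ] <- v
    if (adapt && s %% adapt_block == 0L) {
      rate <- block_acc / adapt_block
      scale <- scale * exp(rate - target_acc)
      block_acc <- 0L
    }
  }
  list(v = v, f = f_cur, best_v = best_v, best_f = best_f,
       acc_rate = n_acc / n_steps, scale = scale, samples = samples)
}

#' Metropolis-Hastings random-walk sampler
#'
#' Samples a target density proportional to `exp(-fn(v))` with Gaussian
#' random-walk proposals, optionally preconditioned by the Cholesky factor
#' of a precision matrix (steps `scale * solve(R, z)`). This is the engine
#' behind [sample_posterior()] and [anneal_to_map()], exposed for generic
#' targets.
#'
#' @param fn Cost function (negative log-density up to a constant).
#' @param v0 Numeric starting vector.
#' @param n_steps Number of proposals.
#' @param scale Step-size multiplier.
#' @param prop_chol Optional upper-triangular Cholesky factor `R` of a
#'   precision matrix; proposals have covariance `scale^2 * (R'R)^-1`.
#' @param seed Optional integer seed.
#' @param record Keep the chain (`$samples`)? Default TRUE.
#' @return List with `samples`, `v`, `f`, `best_v`, `best_f`, `acc_rate`.
#' @export
mh_sample <- function(fn, v0, n_steps, scale = 0.1, prop_chol = NULL,
                      seed = NULL, record = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  mh_engine(fn, v0, n_steps, scale = scale, prop_chol = prop_chol,
            record = record)
}

#' Simulated annealing on a generic cost
#'
#' Metropolis-Hastings at geometrically decreasing temperature
#' (`temp_initial -> 1` by factor `cooling`), with the proposal scale
#' shrinking as `sqrt(T)`; returns the lowest-cost configuration ever
#' visited.
#'
#' @inheritParams mh_sample
#' @param temp_initial,cooling,steps_per_temp Annealing schedule.
#' @param base_scale Proposal scale at temperature 1.
#' @return List with `best_v`, `best_f`, `acc_rate` (at the final level).
#' @export
simulated_annealing <- function(fn, v0, temp_initial = 100, cooling = 0.95,
                                steps_per_temp = 200L, base_scale = 0.1,
                                prop_chol = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(temp_initial >= 1, cooling > 0, cooling < 1)
  temps <- temp_initial
  while (temps[length(temps)] * cooling >= 1) {
    temps <- c(temps, temps[length(temps)] * cooling)
  }
  if (temps[length(temps)] > 1) temps <- c(temps, 1)
  v <- v0
  best_v <- v0
  best_f <- fn(v0)
  acc <- NA_real_
  for (Tk in temps) {
    res <- mh_engine(fn, v, steps_per_temp, scale = base_scale * sqrt(Tk),
                     prop_chol = prop_chol, temperature = Tk)
    v <- res$v
    acc <- res$acc_rate
    if (res$best_f < best_f) {
      best_f <- res$best_f
      best_v <- res$best_v
    }
  }
  list(best_v = best_v, best_f = best_f, acc_rate = acc)
}

# Hessian-based proposal factor at a point (adds a small ridge for safety)
proposal_chol <- function(obj, v) {
  H <- obj$gn_system(v)$H
  dg <- diag(H)
  ridge <- 1e-8 * max(dg, 1)
  chol(H + diag(ridge, nrow(H)))
}

#' Sample the flux posterior
#'
#' Runs a Metropolis-Hastings chain on the concatenated flux vector of all
#' frames, targeting `P(u) ~ exp(-chi2_tot(u) / 2)` — the exact posterior
#' density under Gaussian-distributed standardized residuals (the misfit
#' term of the cost is `sum(r^2/sigma^2)`, so the Gaussian likelihood
#' carries the 1/2). Proposals are Gaussian steps preconditioned by the
#' Cholesky factor of the Gauss-Newton Hessian at the starting point
#' (over-relaxation); the step scale is adapted during burn-in only and
#' frozen afterwards, preserving detailed balance in the sampling phase.
#'
#' @param start Stacked starting flux vector (mmol/gdw/h), typically the
#'   MAP from [anneal_to_map()] or the warm start.
#' @param prep A [prepare_frames()] object.
#' @param hyper A [hyper_params()] object (NA lambdas resolved here).
#' @param bulk Optional bulk series.
#' @param seed Integer seed.
#' @return List with `samples` (n_samples x dim matrix, labelled
#'   `fFRAME:cell`), `acc_rate`, `chi2_trace`, `scale`, `warnings`.
#' @export
sample_posterior <- function(start, prep, hyper = hyper_params(), bulk = NULL,
                             seed = 1L) {
  stopifnot(inherits(prep, "frame_prep"))
  set.seed(seed)
  hyper <- resolve_hyperparams(prep, hyper, bulk)
  obj <- make_objective(prep, hyper$lambda1, hyper$lambda2, hyper$lambda3,
                        bulk, hyper$bulk_statistic)
  R <- proposal_chol(obj, start)
  d <- obj$dim
  log_post_cost <- function(v) obj$chi2(v) / 2   # Gaussian-residual density
  scale0 <- 2.38 / sqrt(d)                       # posterior cov ~ H^-1
  burn <- mh_engine(log_post_cost, start, max(hyper$burn_in, 1L),
                    scale = scale0, prop_chol = R, adapt = TRUE)
  run <- mh_engine(log_post_cost, burn$v, hyper$n_samples, scale = burn$scale,
                   prop_chol = R, record = TRUE)
  colnames(run$samples) <- coord_labels(prep)
  warn <- character()
  if (run$acc_rate < 0.01) warn <- c(warn, "acceptance rate below 1% (step-size pathology)")
  if (run$acc_rate > 0.99) warn <- c(warn, "acceptance rate above 99% (step-size pathology)")
  for (w in warn) warning(w)
  chi2_vals <- apply(run$samples[seq(1, nrow(run$samples),
                                     length.out = min(200, nrow(run$samples))), ,
                                 drop = FALSE], 1, obj$chi2)
  list(samples = run$samples, acc_rate = run$acc_rate,
       best_v = if (run$best_f < burn$best_f) run$best_v else burn$best_v,
       best_f = 2 * min(run$best_f, burn$best_f),   # back on the chi2 scale
       chi2_trace = chi2_vals, scale = burn$scale, warnings = warn,
       hyper = hyper)
}

#' Simulated annealing to the MAP flux configuration
#'
#' Anneals `chi2_tot / T` from `hyper$temp_initial` down to 1 with
#' warm-start-preconditioned proposals, keeps the lowest-cost state ever
#' visited, and (by default) polishes it with a final Gauss-Newton pass on
#' the same objective. The returned cost never exceeds the starting cost.
#'
#' @inheritParams sample_posterior
#' @param polish Run a final Gauss-Newton refinement from the best state?
#' @return List with `v` (MAP), `chi2`, `acc_rate`, `hyper`.
#' @export
anneal_to_map <- function(start, prep, hyper = hyper_params(), bulk = NULL,
                          seed = 1L, polish = TRUE) {
  stopifnot(inherits(prep, "frame_prep"))
  set.seed(seed)
  hyper <- resolve_hyperparams(prep, hyper, bulk)
  obj <- make_objective(prep, hyper$lambda1, hyper$lambda2, hyper$lambda3,
                        bulk, hyper$bulk_statistic)
  R <- proposal_chol(obj, start)
  d <- obj$dim
  ann <- simulated_annealing(obj$chi2, start,
                             temp_initial = hyper$temp_initial,
                             cooling = hyper$cooling,
                             steps_per_temp = hyper$steps_per_temp,
                             base_scale = 2.38 / sqrt(2 * d), prop_chol = R)
  v_best <- ann$best_v
  f_best <- ann$best_f
  if (polish) {
    pol <- gaussian_warm_start(prep, hyper, bulk, v0 = v_best)
    if (pol$chi2 <= f_best) {
      v_best <- pol$v
      f_best <- pol$chi2
    }
  }
  f_start <- obj$chi2(start)
  if (f_start < f_best) {   # best-seen contract: never worse than the start
    v_best <- start
    f_best <- f_start
  }
  list(v = v_best, chi2 = f_best, acc_rate = ann$acc_rate, hyper = hyper)
}

#' Credible intervals from a posterior chain
#'
#' Central posterior-quantile intervals at the requested level plus the
#' 1-sigma-equivalent error (chain standard deviation) per coordinate.
#'
#' @param samples Chain matrix (iterations x coordinates), at least 100
#'   rows.
#' @param level Central probability mass, in [0, 1). `level = 0` gives a
#'   degenerate interval at the median.
#' @return Data frame with `coord`, `lower`, `median`, `upper`, `sigma`.
#' @export
confidence_intervals <- function(samples, level = 0.68) {
  stopifnot(is.matrix(samples), level >= 0, level < 1)
  if (nrow(samples) < 100L) {
    stop("need at least 100 post-burn-in samples for interval estimation")
  }
  a <- (1 - level) / 2
  qs <- apply(samples, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  data.frame(coord = colnames(samples) %||% seq_len(ncol(samples)),
             lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
             sigma = apply(samples, 2, stats::sd),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Infer per-cell fluxes from pH landscapes
#'
#' Full inference pipeline for one experiment: frame preparation,
#' hyperparameter resolution, Gauss-Newton warm start, simulated annealing
#' to the MAP, posterior sampling, and credible intervals. All reported
#' fluxes are in mmol/gdw/h (positive = proton export / acidifying).
#'
#' @param cells,probes Long data frames over frames (see
#'   [read_cell_table()]).
#' @param bulk Optional bulk series data frame (`time_min`,
#'   `bulk_u_mmol_gdw_h`; see [estimate_bulk_efflux()]).
#' @param params A [physical_params()] object.
#' @param hyper A [hyper_params()] object.
#' @param seed Integer seed governing all stochastic stages.
#' @param level Credible-interval level. Default 0.68 (1-sigma
#'   equivalent).
#' @param anneal Run the annealing stage? (Skipping it returns the warm
#'   start as MAP; useful for quick looks.)
#' @param verbose Print per-stage progress?
#' @return Object of class `flux_solution`: list with `fluxes`
#'   (frame_index, time_min, cell_id, u_map_mmol_gdw_h, ci_low, ci_high,
#'   sigma_u), `boundary` (per-frame U with intervals), `residuals` (per
#'   probe per frame, reconstructed minus measured pH), `diagnostics`
#'   (chi2 values, acceptance rate, resolved lambdas, seed), `chain`
#'   (posterior samples), `prep`.
#' @export
infer_fluxes <- function(cells, probes, bulk = NULL,
                         params = physical_params(), hyper = hyper_params(),
                         seed = 1L, level = 0.68, anneal = TRUE,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  prep <- prepare_frames(cells, probes, params,
                         max_displacement_um = hyper$max_displacement_um)
  hyper <- resolve_hyperparams(prep, hyper, bulk)
  say("resolved lambdas: %.4g / %.4g / %.4g", hyper$lambda1, hyper$lambda2,
      hyper$lambda3)
  ws <- gaussian_warm_start(prep, hyper, bulk)
  say("warm start chi2 = %.4g (%d iterations)", ws$chi2, ws$n_iter)
  if (anneal) {
    map <- anneal_to_map(ws$v, prep, hyper, bulk, seed = seed)
    say("MAP chi2 = %.4g (annealing acceptance %.2f)", map$chi2, map$acc_rate)
  } else {
    map <- list(v = ws$v, chi2 = ws$chi2, acc_rate = NA_real_)
  }
  post <- sample_posterior(map$v, prep, hyper, bulk, seed = seed + 1L)
  say("posterior sampling acceptance %.2f", post$acc_rate)
  ci <- confidence_intervals(post$samples, level)

  frames <- prep$frames
  flux_rows <- list()
  boundary_rows <- list()
  resid_rows <- list()
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    idx <- f$offset + seq_len(f$np1)
    vt <- map$v[idx]
    ci_t <- ci[idx, ]
    if (f$np1 > 1L) {
      flux_rows[[k]] <- data.frame(
        frame_index = f$frame_index, time_min = f$time_min,
        cell_id = f$cell_ids,
        u_map_mmol_gdw_h = vt[-1L],
        ci_low = pmin(ci_t$lower[-1L], vt[-1L]),
        ci_high = pmax(ci_t$upper[-1L], vt[-1L]),
        sigma_u = ci_t$sigma[-1L])
    }
    boundary_rows[[k]] <- data.frame(
      frame_index = f$frame_index, time_min = f$time_min,
      U_map_mmol_gdw_h = vt[1L],
      ci_low = min(ci_t$lower[1L], vt[1L]),
      ci_high = max(ci_t$upper[1L], vt[1L]))
    cc <- f$c0 + as.numeric(f$A %*% vt)
    pH_rec <- -log10(pmax(cc, .Machine$double.xmin))
    resid_rows[[k]] <- data.frame(
      frame_index = f$frame_index, probe_id = f$probe_ids,
      pH_measured = f$pH, pH_reconstructed = pH_rec,
      residual = pH_rec - f$pH, sigma = f$sigma)
  }
  structure(
    list(fluxes = do.call(rbind, flux_rows),
         boundary = do.call(rbind, boundary_rows),
         residuals = do.call(rbind, resid_rows),
         chain = post$samples,
         diagnostics = list(chi2_warm_start = ws$chi2, chi2_map = map$chi2,
                            chi2_trace = post$chi2_trace,
                            acceptance_rate = post$acc_rate,
                            annealing_acceptance = map$acc_rate,
                            lambda1 = hyper$lambda1, lambda2 = hyper$lambda2,
                            lambda3 = hyper$lambda3, seed = seed,
                            sampler_warnings = post$warnings),
         hyper = hyper, params = params, prep = prep, level = level,
         map = map$v),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  nf <- length(x$prep$frames)
  cat(sprintf("Flux solution: %d frames, %d cell-frame fluxes\n",
              nf, nrow(x$fluxes)))
  cat(sprintf("  chi2 (MAP)        : %.4g\n", x$diagnostics$chi2_map))
  cat(sprintf("  sampler acceptance: %.2f\n", x$diagnostics$acceptance_rate))
  cat(sprintf("  lambda1/2/3       : %.3g / %.3g / %.3g\n",
              x$diagnostics$lambda1, x$diagnostics$lambda2, x$diagnostics$lambda3))
  frac <- mean(abs(x$residuals$residual) <= x$residuals$sigma)
  cat(sprintf("  residuals within 1 sigma: %.1f%%\n", 100 * frac))
  invisible(x)
}

#' Bulk acidic efflux from a bulk pH time series
#'
#' Converts bulk pH to proton concentration, differentiates by central
#' finite differences (one-sided at the endpoints), scales by the medium
#' volume per cell, and converts to mmol/gdw/h.
#'
#' @param bulk Data frame with `time_min` (monotone) and `bulk_pH` (or
#'   `bulk_concentration` in mol/L, which takes precedence).
#' @param n_cells Number of cells sharing the medium (scalar or per-time
#'   vector).
#' @param params A [physical_params()] object (supplies
#'   `medium_volume_L` and the dry weight).
#' @return Data frame (class `bulk_series`) with `time_min`,
#'   `bulk_concentration`, `bulk_u_mmol_gdw_h`.
#' @export
estimate_bulk_efflux <- function(bulk, n_cells, params = physical_params()) {
  stopifnot(is.data.frame(bulk), "time_min" %in% names(bulk))
  t <- bulk$time_min
  if (length(t) < 3L) stop("need at least 3 time points to estimate bulk efflux")
  if (any(diff(t) <= 0)) stop("time_min must be strictly increasing")
  conc <- if ("bulk_concentration" %in% names(bulk)) bulk$bulk_concentration
          else 10^(-bulk$bulk_pH)
  n <- length(t)
  dcdt <- numeric(n)   # mol/L per minute
  dcdt[1] <- (conc[2] - conc[1]) / (t[2] - t[1])
  dcdt[n] <- (conc[n] - conc[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    k <- 2:(n - 1)
    dcdt[k] <- (conc[k + 1] - conc[k - 1]) / (t[k + 1] - t[k - 1])
  }
  u_native <- dcdt / 60 * params$medium_volume_L / n_cells   # mol/s per cell
  out <- data.frame(time_min = t, bulk_concentration = conc,
                    bulk_u_mmol_gdw_h = convert_flux_units(u_native, params))
  class(out) <- c("bulk_series", "data.frame")
  out
}
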