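# Cost functions, warm start, hyperparameter resolution, bulk efflux.

make_static_frame <- function(n_cells, n_probes, seed, noise_sigma = 0,
                              u_true = NULL, n_frames = 1) {
  # small deterministic experiment wrapper used across inference tests
  generate_experiment("uniform", n_cells = n_cells, n_probes = n_probes,
                      n_frames = n_frames, noise_sigma = noise_sigma,
                      seed = seed)
}

test_that("frame cost equals an independently hand-rolled evaluation", {
  p <- physical_params(background_pH = 6.9)
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      x_um = c(120, 250, 390), y_um = c(100, 320, 210))
  probes <- data.frame(probe_id = paste0("q", 1:5),
                       x_um = c(60, 180, 290, 350, 450),
                       y_um = c(150, 250, 100, 400, 300),
                       pH = c(6.85, 6.92, 6.88, 6.95, 6.90),
                       sigma = c(0.02, 0.03, 0.02, 0.025, 0.02))
  G <- build_distance_matrix(cells, probes, p)
  c0 <- background_concentration(probes$pH, p)
  u <- c(0.3, 2.1, -1.4, 0.8)   # boundary U then cells, mmol/gdw/h
  got <- frame_chi2(u, probes, G, p, lambda1 = 0.7)
  want <- hand_chi2(u, probes, cells, p, c0, lambda1 = 0.7)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("frame cost degenerate cases: perfect fit and flat null model", {
  # ground truth on noise-free synthetic data with lambda1 = 0 costs zero
  ex <- make_static_frame(5, 12, seed = 21, noise_sigma = 0)
  prep <- prepare_frames(ex$cells, ex$probes, ex$params)
  f <- prep$frames[[1]]
  G <- f$A / flux_report_to_native(1, ex$params)
  ut <- ex$truth$u_true_mmol_gdw_h[ex$truth$frame_index == 1]
  pf <- ex$probes[ex$probes$frame_index == 1, ]
  expect_equal(frame_chi2(c(0, ut), pf, G, ex$params, c0 = f$c0, lambda1 = 0),
               0, tolerance = 1e-14)

  # u = 0 with c0 matching all probes exactly: cost zero for any lambda1
  pf2 <- pf
  pf2$pH <- 6.5
  expect_equal(frame_chi2(rep(0, length(ut) + 1), pf2, G, ex$params,
                          c0 = 10^-6.5, lambda1 = 42), 0)

  # unphysical configurations have infinite cost
  expect_equal(frame_chi2(c(0, -1e6, rep(0, length(ut) - 1)), pf, G,
                          ex$params, c0 = f$c0), Inf)
})

test_that("total cost decomposes into frame costs plus temporal and bulk terms", {
  ex <- make_static_frame(4, 10, seed = 5, noise_sigma = 0.01, n_frames = 3)
  prep <- prepare_frames(ex$cells, ex$probes, ex$params)
  u_frames <- lapply(prep$frames, function(f) c(0.2, rep(0.5, length(f$cell_ids))))

  # lambda2 = lambda3 = 0: equals the sum of per-frame costs
  per_frame <- vapply(seq_along(prep$frames), function(k) {
    f <- prep$frames[[k]]
    G <- f$A / flux_report_to_native(1, ex$params)
    pf <- ex$probes[ex$probes$frame_index == f$frame_index, ]
    frame_chi2(u_frames[[k]], pf, G, ex$params, c0 = f$c0, lambda1 = 0.3)
  }, 0)
  expect_equal(total_chi2(u_frames, prep, lambda1 = 0.3), sum(per_frame),
               tolerance = 1e-12)

  # constant fluxes across frames: temporal term contributes exactly zero
  expect_equal(total_chi2(u_frames, prep, lambda1 = 0.3, lambda2 = 7),
               sum(per_frame), tolerance = 1e-12)

  # hand-evaluated temporal penalty: one tracked cell, u = (1, 3), lambda2 = 0.5
  cells2 <- data.frame(frame_index = rep(1:2, each = 1), time_min = c(0, 10),
                       cell_id = "a", x_um = c(250, 252), y_um = c(250, 250))
  probes2 <- do.call(rbind, lapply(1:2, function(t)
    data.frame(frame_index = t, time_min = (t - 1) * 10,
               probe_id = paste0("q", 1:3), x_um = c(100, 300, 400),
               y_um = c(100, 300, 150), pH = 6.8, sigma = 0.02)))
  prep2 <- prepare_frames(cells2, probes2, physical_params(background_pH = 6.8))
  u2 <- list(c(0, 1), c(0, 3))
  base <- total_chi2(u2, prep2, lambda2 = 0)
  expect_equal(total_chi2(u2, prep2, lambda2 = 0.5) - base, 0.5 * (3 - 1)^2)

  # lambda3 without bulk data is an instructive error
  expect_error(total_chi2(u_frames, prep, lambda3 = 1), "bulk")
})

test_that("warm start solves identifiable and prior-dominated limits", {
  # noise-free single source: recovered within 1e-6 relative at tiny lambda1
  ex <- make_static_frame(1, 30, seed = 8, noise_sigma = 0)
  prep <- prepare_frames(ex$cells, ex$probes, ex$params)
  ws <- gaussian_warm_start(prep, hyper_params(lambda1 = 1e-10, lambda2 = 0,
                                               lambda3 = 0))
  u_true <- ex$truth$u_true_mmol_gdw_h
  expect_equal(ws$v[2], u_true, tolerance = 1e-6)

  # infinite prior weight shrinks every cell flux to zero
  ws_inf <- gaussian_warm_start(prep, hyper_params(lambda1 = 1e12, lambda2 = 0,
                                                   lambda3 = 0))
  expect_lt(max(abs(ws_inf$v[-1])), 1e-6)

  # underdetermined frame at lambda1 = 0 gives the multicollinearity error
  ex2 <- make_static_frame(8, 3, seed = 9, noise_sigma = 0.01)
  prep2 <- prepare_frames(ex2$cells, ex2$probes, ex2$params)
  expect_error(
    gaussian_warm_start(prep2, hyper_params(lambda1 = 0, lambda2 = 0, lambda3 = 0)),
    "lambda1")
})

test_that("warm start matches a brute-force minimizer of the exact cost", {
  ex <- make_static_frame(3, 20, seed = 13, noise_sigma = 0.01)
  prep <- prepare_frames(ex$cells, ex$probes, ex$params)
  hy <- hyper_params(lambda1 = 0.01, lambda2 = 0, lambda3 = 0)
  ws <- gaussian_warm_start(prep, hy)
  obj <- function(v) total_chi2(list(v), prep, lambda1 = 0.01)
  oracle <- stats::optim(rep(0, prep$dim), obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))
  expect_lt(obj(ws$v), oracle$value + 1e-6)
  cell_idx <- 2:prep$dim
  expect_equal(ws$v[cell_idx], oracle$par[cell_idx], tolerance = 0.01)
})

test_that("regularization monotonicity of the fitted optimum", {
  ex <- make_static_frame(6, 15, seed = 31, noise_sigma = 0.02, n_frames = 3)
  prep <- prepare_frames(ex$cells, ex$probes, ex$params)

  l2_norm <- vapply(c(0.05, 0.5, 5, 50), function(l1) {
    ws <- gaussian_warm_start(prep, hyper_params(lambda1 = l1, lambda2 = 0.1,
                                                 lambda3 = 0))
    sum(unlist(lapply(prep$frames, function(f)
      ws$v[f$offset + 1 + seq_along(f$cell_ids)]^2)))
  }, 0)
  expect_true(all(diff(l2_norm) <= 1e-8))

  pairs_ss <- vapply(c(0, 0.5, 5, 50), function(l2) {
    ws <- gaussian_warm_start(prep, hyper_params(lambda1 = 0.2, lambda2 = l2,
                                                 lambda3 = 0))
    tp <- phfluxnet:::tracking_pairs(prep)
    sum((ws$v[tp$i2] - ws$v[tp$i1])^2)
  }, 0)
  expect_true(all(diff(pairs_ss) <= 1e-8))
})

test_that("hyperparameter resolution is data-driven and overridable", {
  ex <- make_static_frame(5, 20, seed = 17, noise_sigma = 0.02, n_frames = 2)
  prep <- prepare_frames(ex$cells, ex$probes, ex$params)
  hy <- resolve_hyperparams(prep, hyper_params())
  expect_true(is.finite(hy$lambda1) && hy$lambda1 > 0)
  expect_equal(hy$lambda2, hy$lambda1 / 10)
  expect_equal(hy$lambda3, 0)    # no bulk series supplied

  bulk <- make_bulk_series(ex)
  hy2 <- resolve_hyperparams(prep, hyper_params(), bulk)
  chi0 <- sum(vapply(prep$frames, function(f)
    sum(((f$pH + log10(f$c0)) / f$sigma)^2), 0))
  ub <- bulk$bulk_u_mmol_gdw_h
  expect_equal(hy2$lambda3, 0.1 * chi0 / sum(ub^2))

  hy3 <- resolve_hyperparams(prep, hyper_params(lambda1 = 2), bulk)
  expect_equal(hy3$lambda1, 2)
  expect_equal(hy3$lambda2, 0.2)
})

test_that("bulk efflux estimation follows the finite-difference closed form", {
  p <- physical_params(medium_volume_L = 2e-4)
  # linear [H+] growth at rate r mol/L/min shared by N cells
  r <- 3e-10
  t <- seq(0, 100, by = 10)
  conc <- 1e-7 + r * t
  bulk <- data.frame(time_min = t, bulk_pH = -log10(conc))
  est <- estimate_bulk_efflux(bulk, n_cells = 40, p)
  want <- convert_flux_units(r / 60 * 2e-4 / 40, p)
  interior <- 2:(length(t) - 1)
  expect_equal(est$bulk_u_mmol_gdw_h[interior], rep(want, length(interior)),
               tolerance = 1e-9)

  # constant pH: zero efflux everywhere
  flat <- data.frame(time_min = t, bulk_pH = rep(7.1, length(t)))
  expect_equal(estimate_bulk_efflux(flat, 40, p)$bulk_u_mmol_gdw_h,
               rep(0, length(t)))

  # time reversal flips the sign of the interior estimate
  rev_bulk <- data.frame(time_min = t, bulk_pH = rev(-log10(conc)))
  est_rev <- estimate_bulk_efflux(rev_bulk, 40, p)
  expect_equal(est_rev$bulk_u_mmol_gdw_h[interior],
               -rev(est$bulk_u_mmol_gdw_h[interior]), tolerance = 1e-9)

  expect_error(estimate_bulk_efflux(bulk[1:2, ], 40, p), "3 time points")
})

test_that("credible intervals come from chain quantiles", {
  set.seed(4)
  samples <- cbind(a = rnorm(5000, 2, 0.5), b = rnorm(5000, -1, 2))
  ci <- confidence_intervals(samples, level = 0.68)
  expect_equal(ci$sigma, c(0.5, 2), tolerance = 0.05)
  expect_equal(ci$upper - ci$lower, 2 * stats::qnorm(0.84) * c(0.5, 2),
               tolerance = 0.1)
  ci0 <- confidence_intervals(samples, level = 0)
  expect_equal(ci0$lower, ci0$upper)
  expect_equal(ci0$lower, ci0$median)
  expect_error(confidence_intervals(samples[1:50, ]), "100")
})
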