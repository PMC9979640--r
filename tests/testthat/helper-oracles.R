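# Independent oracles used across tests. These deliberately re-derive
# quantities from first principles (explicit loops, literal formulas)
# rather than calling package internals.

# hand-rolled per-frame cost: sum over probes of squared standardized
# residual + lambda1 * sum over cells of u^2 (boundary excluded)
hand_chi2 <- function(u_report, probes, cells, params, c0, lambda1) {
  dw_g <- params$cell_dry_weight_ng * 1e-9
  u_native <- u_report * dw_g / 3.6e6
  kfac <- 1e15 / (4 * pi * params$diffusion_um2_s)
  L <- params$frame_size_um
  nb <- params$boundary_points
  per <- seq(0, 4 * L, length.out = nb + 1)[-(nb + 1)]
  bpts <- t(vapply(per, function(s) {
    if (s < L) c(s, 0)
    else if (s < 2 * L) c(L, s - L)
    else if (s < 3 * L) c(3 * L - s, L)
    else c(0, 4 * L - s)
  }, c(0, 0)))
  tot <- 0
  for (m in seq_len(nrow(probes))) {
    conc <- c0
    db <- pmax(sqrt((bpts[, 1] - probes$x_um[m])^2 +
                    (bpts[, 2] - probes$y_um[m])^2), params$min_distance_um)
    conc <- conc + u_native[1] * mean(kfac / db)
    for (i in seq_len(nrow(cells))) {
      d <- sqrt((cells$x_um[i] - probes$x_um[m])^2 +
                (cells$y_um[i] - probes$y_um[m])^2)
      d <- max(d, params$min_distance_um)
      conc <- conc + u_native[i + 1] * kfac / d
    }
    tot <- tot + ((probes$pH[m] - (-log10(conc))) / probes$sigma[m])^2
  }
  tot + lambda1 * sum(u_report[-1]^2)
}

# conservative finite-volume solver for the spherically symmetric Laplace
# problem (r^2 c')' = 0 with an inner Neumann flux condition matched to
# the source strength and far-field Dirichlet c = c0. Independent check
# of the analytic monopole kernel.
radial_fd_solver <- function(u_native, D, c0, r_in = 6, r_out = 1e5, n = 1200) {
  r <- exp(seq(log(r_in), log(r_out), length.out = n))
  rf <- sqrt(r[-1] * r[-n])              # face radii (log midpoint)
  q <- u_native * 1e15 / (4 * pi * D)    # = -r^2 c' for the matched source
  A <- matrix(0, n, n)
  b <- numeric(n)
  # face conductances g_i = rf^2 / dr between nodes i, i+1
  g <- rf^2 / diff(r)
  # node 1: flux through face 1 equals the source flux
  A[1, 1] <- -g[1]; A[1, 2] <- g[1]; b[1] <- -q
  for (i in 2:(n - 1)) {                 # conservation at interior nodes
    A[i, i - 1] <- g[i - 1]
    A[i, i] <- -(g[i - 1] + g[i])
    A[i, i + 1] <- g[i]
    b[i] <- 0
  }
  A[n, n] <- 1; b[n] <- c0               # far-field Dirichlet
  cc <- solve(A, b)
  list(r = r, c = cc)
}

# minimal exchange_graph constructor for topology-only tests
manual_graph <- function(node_ids, edges, frame_index = 1L) {
  structure(
    list(nodes = data.frame(cell_id = node_ids,
                            u = rep(0, length(node_ids)),
                            x_um = rep(0, length(node_ids)),
                            y_um = rep(0, length(node_ids))),
         edges = edges, leakage = 0, threshold = 0, dist_exponent = 1,
         frame_index = frame_index, time_min = 0, note = NULL),
    class = "exchange_graph")
}

# chi-square goodness of fit of a degree histogram against its Poisson
# null, pooling bins with small expected counts
poisson_gof_p <- function(hist_df) {
  obs <- hist_df$count
  expd <- hist_df$poisson_expected
  # pool bins until every expected count >= 5
  while (length(expd) > 2 && min(expd) < 5) {
    i <- which.min(expd)
    j <- if (i == length(expd)) i - 1L else i + 1L
    expd[j] <- expd[j] + expd[i]; obs[j] <- obs[j] + obs[i]
    expd <- expd[-i]; obs <- obs[-i]
  }
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}

# regularization weights matched to the generator's AR(1) flux process
# (stationary sd tau = 1, rho = 0.95) under the Gaussian-residual
# posterior exp(-chi2/2): lambda1 = 1/tau^2, lambda2 = 1/(tau^2 (1-rho^2))
matched_hyper <- function(...) {
  rho <- 0.95
  hyper_params(lambda1 = 1, lambda2 = 1 / (1 - rho^2), lambda3 = 0, ...)
}
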