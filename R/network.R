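# Cell-to-cell exchange network. A proton released by an exporting cell i
# diffuses until absorbed; the absorption probability at importer j decays
# with distance (it solves the Laplace equation in the absorbing points),
# giving the pairwise flux
#   F_ij = u_i * (|u_j| / d_ij) / Z_i,   Z_i = sum_k |u_k| / d_ik,
# so that the out-fluxes of each donor sum exactly to u_i.

#' Pairwise exchange fluxes from a per-frame flux vector
#'
#' Builds the weighted directed exchange graph of one frame: edges run
#' from donors (u > 0) to acceptors (u < 0) with weight
#' `F_ij = u_i * (|u_j| / d_ij^p) / Z_i`, normalized so the out-weights of
#' every donor sum to its flux. The boundary flux is never a node. If the
#' frame has no importers, donors get no edges and the condition is
#' recorded in the `note` field.
#'
#' @param fluxes Data frame with `cell_id` and `u` (mmol/gdw/h) for one
#'   frame (e.g. a slice of a [infer_fluxes()] `$fluxes` table with `u =
#'   u_map_mmol_gdw_h`).
#' @param cells Cell positions for the same frame (`cell_id`, `x_um`,
#'   `y_um`).
#' @param params A [physical_params()] object (supplies the distance
#'   clamp for coincident positions).
#' @param dist_exponent Exponent p on distance in the absorption weight.
#'   Default 1 (monopole absorption heuristic).
#' @param frame_index,time_min Optional frame annotations.
#' @return Object of class `exchange_graph`: list with `nodes` (cell_id,
#'   u, x_um, y_um), `edges` (donor, acceptor, weight), `leakage`
#'   (sum of donor fluxes minus total acceptor magnitude), `threshold`
#'   (0 for the raw graph), `frame_index`, `time_min`, `note`.
#' @examples
#' fl <- data.frame(cell_id = c("a", "b"), u = c(5, -5))
#' pos <- data.frame(cell_id = c("a", "b"), x_um = c(0, 30), y_um = c(0, 0))
#' g <- pairwise_fluxes(fl, pos)
#' g$edges  # single edge of weight 5, independent of distance
#' @export
pairwise_fluxes <- function(fluxes, cells, params = physical_params(),
                            dist_exponent = 1, frame_index = NA_integer_,
                            time_min = NA_real_) {
  stopifnot(is.data.frame(fluxes), all(c("cell_id", "u") %in% names(fluxes)),
            is.data.frame(cells),
            all(c("cell_id", "x_um", "y_um") %in% names(cells)))
  pos <- cells[match(fluxes$cell_id, cells$cell_id), ]
  if (any(is.na(pos$x_um))) {
    stop("missing positions for cells: ",
         paste(fluxes$cell_id[is.na(pos$x_um)], collapse = ", "))
  }
  u <- fluxes$u
  ids <- as.character(fluxes$cell_id)
  don <- which(u > 0)
  acc <- which(u < 0)
  note <- NULL
  edges <- data.frame(donor = character(), acceptor = character(),
                      weight = numeric())
  if (length(don) && length(acc)) {
    d <- sqrt(outer(pos$x_um[don], pos$x_um[acc], "-")^2 +
              outer(pos$y_um[don], pos$y_um[acc], "-")^2)
    if (any(d < params$min_distance_um)) {
      warning("coincident or near-coincident donor/acceptor positions; ",
              "distances clamped to ", params$min_distance_um, " um")
      d <- pmax(d, params$min_distance_um)
    }
    w <- sweep(1 / d^dist_exponent, 2, abs(u[acc]), `*`)   # |u_j| / d_ij^p
    z <- rowSums(w)
    f_mat <- (u[don] / z) * w
    edges <- data.frame(
      donor = rep(ids[don], times = length(acc)),
      acceptor = rep(ids[acc], each = length(don)),
      weight = as.numeric(f_mat))
    edges <- edges[edges$weight > 0, ]
    rownames(edges) <- NULL
  } else if (length(don) && !length(acc)) {
    note <- "no importers in frame: donors have no edges"
  }
  structure(
    list(nodes = data.frame(cell_id = ids, u = u,
                            x_um = pos$x_um, y_um = pos$y_um),
         edges = edges,
         leakage = sum(u[don]) - sum(abs(u[acc])),
         threshold = 0, dist_exponent = dist_exponent,
         frame_index = frame_index, time_min = time_min, note = note),
    class = "exchange_graph"
  )
}

#' @export
print.exchange_graph <- function(x, ...) {
  cat(sprintf("Exchange graph%s: %d cells, %d edges (threshold %g mmol/gdw/h)\n",
              if (is.na(x$frame_index)) "" else sprintf(" [frame %d]", x$frame_index),
              nrow(x$nodes), nrow(x$edges), x$threshold))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Threshold an exchange graph
#'
#' Keeps edges whose weight strictly exceeds the threshold (the detection
#' sensitivity); all nodes are retained even if isolated.
#'
#' @param g An [pairwise_fluxes()] graph.
#' @param threshold Edge threshold in mmol/gdw/h (>= 0). Default 0.5.
#' @return The thresholded `exchange_graph`.
#' @export
threshold_graph <- function(g, threshold = 0.5) {
  stopifnot(inherits(g, "exchange_graph"), threshold >= 0)
  g$edges <- g$edges[g$edges$weight > threshold, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$threshold <- threshold
  g
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    g$edges, directed = TRUE,
    vertices = data.frame(name = g$nodes$cell_id))
}

#' Graph-level summary statistics
#'
#' Average and maximum node degree (on the undirected projection: each
#' edge contributes one to both endpoints), the size of the largest
#' connected component (isolated nodes are components of size 1), in- and
#' out-degrees, the degree histogram and its Poisson null
#' `n * exp(-<k>) <k>^k / k!` with the same mean.
#'
#' @param g An `exchange_graph` (thresholded or raw).
#' @return Object of class `graph_summary`: list with `n_nodes`,
#'   `n_edges`, `average_degree`, `max_degree`, `lcc_size`,
#'   `degree_histogram` (data frame `k`, `count`, `poisson_expected`),
#'   `degrees`, `in_degrees`, `out_degrees`, `leakage`, `frame_index`,
#'   `time_min`, `threshold`.
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "exchange_graph"))
  if (nrow(g$nodes) == 0L) stop("graph has no nodes")
  ig <- as_igraph(g)
  deg <- igraph::degree(ig, mode = "all")
  comp <- igraph::components(ig, mode = "weak")
  kmax <- max(deg)
  hist_counts <- tabulate(deg + 1L, nbins = kmax + 1L)
  kk <- 0:kmax
  n <- nrow(g$nodes)
  structure(
    list(n_nodes = n, n_edges = nrow(g$edges),
         average_degree = mean(deg), max_degree = kmax,
         lcc_size = max(comp$csize),
         degree_histogram = data.frame(
           k = kk, count = hist_counts,
           poisson_expected = n * stats::dpois(kk, mean(deg))),
         degrees = deg,
         in_degrees = igraph::degree(ig, mode = "in"),
         out_degrees = igraph::degree(ig, mode = "out"),
         leakage = g$leakage,
         frame_index = g$frame_index, time_min = g$time_min,
         threshold = g$threshold),
    class = "graph_summary"
  )
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("Graph summary%s: %d nodes, %d edges\n",
              if (is.na(x$frame_index)) "" else sprintf(" [frame %d]", x$frame_index),
              x$n_nodes, x$n_edges))
  cat(sprintf("  <k> = %.3g, max degree = %d, LCC size = %d\n",
              x$average_degree, x$max_degree, x$lcc_size))
  invisible(x)
}

#' Exchange graphs for every frame of a flux solution
#'
#' Convenience wrapper: slices a [infer_fluxes()] solution (or any table
#' with `frame_index`, `cell_id` and a flux column) per frame, builds the
#' raw exchange graph, and thresholds it.
#'
#' @param fluxes Flux table (`frame_index`, `time_min`, `cell_id`, and the
#'   column named in `flux_col`), or a `flux_solution`.
#' @param cells Long cell-position table over frames.
#' @param threshold Edge threshold (mmol/gdw/h).
#' @param params A [physical_params()] object.
#' @param flux_col Name of the flux column. Default `u_map_mmol_gdw_h`.
#' @param dist_exponent Distance exponent, see [pairwise_fluxes()].
#' @return Named list of `exchange_graph`s, one per frame.
#' @export
exchange_graphs <- function(fluxes, cells, threshold = 0.5,
                            params = physical_params(),
                            flux_col = "u_map_mmol_gdw_h",
                            dist_exponent = 1) {
  if (inherits(fluxes, "flux_solution")) fluxes <- fluxes$fluxes
  stopifnot(is.data.frame(fluxes), flux_col %in% names(fluxes))
  out <- list()
  for (fi in sort(unique(fluxes$frame_index))) {
    fl <- fluxes[fluxes$frame_index == fi, ]
    g <- pairwise_fluxes(
      data.frame(cell_id = fl$cell_id, u = fl[[flux_col]]),
      cells[cells$frame_index == fi, ], params,
      dist_exponent = dist_exponent, frame_index = fi,
      time_min = if ("time_min" %in% names(fl)) fl$time_min[1] else NA_real_)
    out[[as.character(fi)]] <- threshold_graph(g, threshold)
  }
  out
}

#' Dipole-motif time trace
#'
#' Aligns, across frames, the exchange flux between two cells and both
#' cells' own fluxes, and reports the Pearson correlation between the two
#' cells' absolute flux series (dipole-forming cells exchange in a
#' mutually correlated way). The correlation is `NA` (with an explanatory
#' attribute) for degenerate series: fewer than 2 frames or zero variance.
#'
#' @param graphs List of `exchange_graph`s over frames (e.g. from
#'   [exchange_graphs()], raw or thresholded).
#' @param cell_pair Character vector of two cell ids.
#' @return Data frame (class `motif_trace`) with `frame_index`,
#'   `time_min`, `F` (exchange flux between the pair, 0 if no edge),
#'   `u_1`, `u_2`; attributes `correlation` and possibly
#'   `correlation_note`.
#' @export
motif_trace <- function(graphs, cell_pair) {
  stopifnot(length(cell_pair) == 2L)
  rows <- lapply(graphs, function(g) {
    m <- match(cell_pair, g$nodes$cell_id)
    if (any(is.na(m))) {
      stop(sprintf("cell '%s' is not tracked in frame %s",
                   cell_pair[which(is.na(m))[1]], g$frame_index))
    }
    e <- g$edges
    sel <- (e$donor == cell_pair[1] & e$acceptor == cell_pair[2]) |
           (e$donor == cell_pair[2] & e$acceptor == cell_pair[1])
    data.frame(frame_index = g$frame_index, time_min = g$time_min,
               F = if (any(sel)) sum(e$weight[sel]) else 0,
               u_1 = g$nodes$u[m[1]], u_2 = g$nodes$u[m[2]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  note <- NULL
  if (nrow(out) < 2L) {
    rho <- NA_real_
    note <- "correlation undefined: single-frame series"
  } else if (stats::sd(abs(out$u_1)) == 0 || stats::sd(abs(out$u_2)) == 0) {
    rho <- NA_real_
    note <- "correlation undefined: zero variance in a flux series"
  } else {
    rho <- stats::cor(abs(out$u_1), abs(out$u_2))
  }
  attr(out, "correlation") <- rho
  if (!is.null(note)) attr(out, "correlation_note") <- note
  class(out) <- c("motif_trace", "data.frame")
  out
}

#' Pooled flux distribution with Gaussian fit and excess-tail report
#'
#' Pools flux values (e.g. across all frames of a solution), fits a
#' Gaussian by moments, and reports the fraction of values beyond 3 fitted
#' standard deviations together with the Gaussian expectation of that
#' fraction (2 * pnorm(-3) ~ 0.0027). Heavy-tailed flux populations show
#' an excess-tail fraction far above the Gaussian expectation.
#'
#' @param u Numeric vector of fluxes (mmol/gdw/h), length >= 2, or a
#'   `flux_solution`.
#' @param breaks Passed to [graphics::hist()]-style binning via
#'   [base::cut()]; default `"Sturges"` handled by [hist()].
#' @return Object of class `flux_distribution`: list with `mean`, `sd`,
#'   `n`, `excess_tail_fraction`, `gaussian_expectation`, `histogram`
#'   (data frame `mid`, `count`, `density`, `gaussian_density`).
#' @export
flux_distribution <- function(u, breaks = "Sturges") {
  if (inherits(u, "flux_solution")) u <- u$fluxes$u_map_mmol_gdw_h
  u <- u[is.finite(u)]
  if (length(u) < 2L) stop("need at least 2 flux values")
  m <- mean(u)
  s <- stats::sd(u)
  h <- graphics::hist(u, breaks = breaks, plot = FALSE)
  structure(
    list(mean = m, sd = s, n = length(u),
         excess_tail_fraction = if (s > 0) mean(abs(u - m) > 3 * s) else 0,
         gaussian_expectation = 2 * stats::pnorm(-3),
         histogram = data.frame(
           mid = h$mids, count = h$counts, density = h$density,
           gaussian_density = stats::dnorm(h$mids, m, s))),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("Flux distribution: n = %d, mean = %.3g, sd = %.3g mmol/gdw/h\n",
              x$n, x$mean, x$sd))
  cat(sprintf("  beyond 3 sd: %.4f (Gaussian expectation %.4f)\n",
              x$excess_tail_fraction, x$gaussian_expectation))
  invisible(x)
}

#' Per-frame graph summaries as a table
#'
#' @param graphs List of `exchange_graph`s (e.g. [exchange_graphs()]).
#' @return Data frame with one row per frame: `frame_index`, `time_min`,
#'   `avg_degree`, `max_degree`, `lcc_size`, `n_nodes`, `n_edges`,
#'   `leakage`.
#' @export
summarise_graphs <- function(graphs) {
  rows <- lapply(graphs, function(g) {
    s <- graph_summary(g)
    data.frame(frame_index = s$frame_index, time_min = s$time_min,
               avg_degree = s$average_degree, max_degree = s$max_degree,
               lcc_size = s$lcc_size, n_nodes = s$n_nodes,
               n_edges = s$n_edges, leakage = s$leakage)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
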