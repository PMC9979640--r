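# Exchange network: pairwise fluxes, thresholding, graph summaries,
# motif traces, flux distribution.

test_that("pairwise fluxes follow the normalized absorption weights", {
  p <- physical_params()
  # one donor, one acceptor: the single edge carries the whole donor flux,
  # independent of distance
  g <- pairwise_fluxes(
    data.frame(cell_id = c("d", "a"), u = c(5, -5)),
    data.frame(cell_id = c("d", "a"), x_um = c(100, 137.3), y_um = c(50, 50)), p)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 5)
  expect_equal(g$edges$donor, "d")

  # donor +6 with acceptors of magnitude 2 and 1 at equal distance: 4 and 2
  g2 <- pairwise_fluxes(
    data.frame(cell_id = c("d", "A", "B"), u = c(6, -2, -1)),
    data.frame(cell_id = c("d", "A", "B"),
               x_um = c(100, 100, 100), y_um = c(100, 110, 90)), p)
  wA <- g2$edges$weight[g2$edges$acceptor == "A"]
  wB <- g2$edges$weight[g2$edges$acceptor == "B"]
  expect_equal(wA, 4)
  expect_equal(wB, 2)

  # all-exporter frame: zero edges, condition reported
  g3 <- pairwise_fluxes(
    data.frame(cell_id = c("d1", "d2"), u = c(3, 1)),
    data.frame(cell_id = c("d1", "d2"), x_um = c(10, 400), y_um = c(10, 400)), p)
  expect_equal(nrow(g3$edges), 0)
  expect_match(g3$note, "no importers")

  # leakage is the net donor excess
  expect_equal(g2$leakage, 6 - 3)
  expect_equal(g3$leakage, 4)
})

test_that("donor out-weights sum exactly to the donor flux (conservation)", {
  p <- physical_params()
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(3:25, 1)
    u <- rnorm(n, 0, 10^runif(1, -1, 1.5))
    pos <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      x_um = runif(n, 0, 500), y_um = runif(n, 0, 500))
    g <- suppressWarnings(
      pairwise_fluxes(data.frame(cell_id = pos$cell_id, u = u), pos, p))
    if (nrow(g$edges) == 0) next
    out <- tapply(g$edges$weight, g$edges$donor, sum)
    want <- u[match(names(out), pos$cell_id)]
    expect_equal(as.numeric(out), want, tolerance = 1e-12)
  }
})

test_that("thresholding is strict and preserves nodes", {
  p <- physical_params()
  # equal distances make edge weights proportional to acceptor magnitudes:
  # donor 1.5 splits into exactly 0.4, 0.5, 0.6
  g <- pairwise_fluxes(
    data.frame(cell_id = c("d", "a1", "a2", "a3"), u = c(1.5, -4, -5, -6)),
    data.frame(cell_id = c("d", "a1", "a2", "a3"),
               x_um = c(250, 250, 250 + 20 * sin(2 * pi / 3), 250 + 20 * sin(4 * pi / 3)),
               y_um = c(250, 270, 250 + 20 * cos(2 * pi / 3), 250 + 20 * cos(4 * pi / 3))), p)
  expect_equal(sort(g$edges$weight), c(0.4, 0.5, 0.6))

  expect_equal(nrow(threshold_graph(g, 0)$edges), 3)       # all positive pass
  t05 <- threshold_graph(g, 0.5)
  expect_equal(nrow(t05$edges), 1)                         # strict inequality
  expect_equal(t05$edges$weight, 0.6)
  tbig <- threshold_graph(g, 10)
  expect_equal(nrow(tbig$edges), 0)
  expect_equal(nrow(tbig$nodes), 4)                        # nodes retained
})

test_that("graph summaries match hand counts", {
  empty <- manual_graph(sprintf("n%02d", 1:10),
                        data.frame(donor = character(), acceptor = character(),
                                   weight = numeric()))
  s <- graph_summary(empty)
  expect_equal(s$average_degree, 0)
  expect_equal(s$max_degree, 0)
  expect_equal(s$lcc_size, 1)
  expect_equal(sum(s$degree_histogram$count), 10)

  dip <- manual_graph(sprintf("n%02d", 1:10),
                      data.frame(donor = "n01", acceptor = "n02", weight = 2))
  sd_ <- graph_summary(dip)
  expect_equal(sd_$average_degree, 0.2)
  expect_equal(sd_$max_degree, 1)
  expect_equal(sd_$lcc_size, 2)

  star <- manual_graph(c("hub", paste0("a", 1:5)),
                       data.frame(donor = "hub", acceptor = paste0("a", 1:5),
                                  weight = 2))
  ss <- graph_summary(star)
  expect_equal(ss$max_degree, 5)
  expect_equal(ss$lcc_size, 6)
  expect_equal(ss$average_degree, 10 / 6)

  expect_error(graph_summary(manual_graph(character(),
                                          data.frame(donor = character(),
                                                     acceptor = character(),
                                                     weight = numeric()))),
               "no nodes")
})

test_that("summary statistics are monotone in the threshold", {
  p <- physical_params()
  set.seed(3)
  for (rep in 1:15) {
    n <- 30
    u <- rnorm(n, 0, 3)
    pos <- data.frame(cell_id = sprintf("c%02d", 1:n),
                      x_um = runif(n, 0, 500), y_um = runif(n, 0, 500))
    g <- suppressWarnings(
      pairwise_fluxes(data.frame(cell_id = pos$cell_id, u = u), pos, p))
    stats_at <- vapply(c(0, 0.1, 0.3, 0.5, 1, 2), function(tau) {
      s <- graph_summary(threshold_graph(g, tau))
      c(s$average_degree, s$max_degree, s$lcc_size)
    }, numeric(3))
    expect_true(all(diff(stats_at[1, ]) <= 1e-12))
    expect_true(all(diff(stats_at[2, ]) <= 0))
    expect_true(all(diff(stats_at[3, ]) <= 0))
  }
})

test_that("the network is scale covariant under flux rescaling", {
  p <- physical_params()
  set.seed(11)
  n <- 20
  u <- rnorm(n, 0, 2)
  pos <- data.frame(cell_id = sprintf("c%02d", 1:n),
                    x_um = runif(n, 0, 500), y_um = runif(n, 0, 500))
  s <- 3.7
  g1 <- pairwise_fluxes(data.frame(cell_id = pos$cell_id, u = u), pos, p)
  gs <- pairwise_fluxes(data.frame(cell_id = pos$cell_id, u = s * u), pos, p)
  ord <- function(e) e[order(e$donor, e$acceptor), ]
  e1 <- ord(g1$edges); es <- ord(gs$edges)
  expect_equal(es$weight, s * e1$weight)
  # thresholded topology at s * tau matches the original at tau exactly
  tau <- 0.4
  t1 <- ord(threshold_graph(g1, tau)$edges)
  ts <- ord(threshold_graph(gs, s * tau)$edges)
  expect_equal(ts[, c("donor", "acceptor")], t1[, c("donor", "acceptor")])
})

test_that("degree distributions separate Poisson-like from hub-dominated graphs", {
  set.seed(21)
  n <- 400
  ig <- igraph::sample_gnp(n, 3 / n, directed = FALSE)
  el <- igraph::as_edgelist(ig)
  er <- manual_graph(as.character(1:n),
                     data.frame(donor = as.character(el[, 1]),
                                acceptor = as.character(el[, 2]), weight = 1))
  p_er <- poisson_gof_p(graph_summary(er)$degree_histogram)
  expect_gt(p_er, 0.01)

  hub <- manual_graph(c("hub", paste0("a", 1:99)),
                      data.frame(donor = "hub", acceptor = paste0("a", 1:40),
                                 weight = 1))
  p_hub <- poisson_gof_p(graph_summary(hub)$degree_histogram)
  expect_lt(p_hub, 0.01)
})

test_that("motif traces align pair series and report |u| correlation", {
  p <- physical_params()
  set.seed(5)
  nf <- 20
  amp <- 10 + 3 * sin(seq(0, 2 * pi, length.out = nf))
  graphs <- lapply(seq_len(nf), function(t) {
    u_d <- amp[t] * (1 + 0.05 * rnorm(1))
    u_a <- -amp[t] * (1 + 0.05 * rnorm(1))
    pairwise_fluxes(
      data.frame(cell_id = c("d", "a"), u = c(u_d, u_a)),
      data.frame(cell_id = c("d", "a"), x_um = c(100, 120), y_um = c(50, 50)),
      p, frame_index = t, time_min = 10 * (t - 1))
  })
  tr <- motif_trace(graphs, c("d", "a"))
  expect_equal(nrow(tr), nf)
  expect_true(all(tr$F > 0))
  expect_gte(attr(tr, "correlation"), 0.9)

  # constant pair: zero variance, correlation undefined
  const <- lapply(1:3, function(t) pairwise_fluxes(
    data.frame(cell_id = c("d", "a"), u = c(2, -2)),
    data.frame(cell_id = c("d", "a"), x_um = c(100, 120), y_um = c(50, 50)),
    p, frame_index = t))
  trc <- motif_trace(const, c("d", "a"))
  expect_true(is.na(attr(trc, "correlation")))
  expect_match(attr(trc, "correlation_note"), "variance")

  # single frame: undefined
  tr1 <- motif_trace(const[1], c("d", "a"))
  expect_true(is.na(attr(tr1, "correlation")))

  # untracked cell: error names the frame
  expect_error(motif_trace(const, c("d", "zz")), "zz")
})

test_that("flux distribution reports Gaussian fit and excess tails", {
  set.seed(8)
  x <- rnorm(2e5)
  fd <- flux_distribution(x)
  band <- 3 * sqrt(0.0027 * (1 - 0.0027) / 2e5)
  expect_lt(abs(fd$excess_tail_fraction - fd$gaussian_expectation), band + 5e-4)

  two <- flux_distribution(c(1, 3))
  expect_equal(two$mean, 2)
  expect_equal(two$sd, sd(c(1, 3)))

  # Gaussian core with 5% outliers at 10 sd: tails far above the Gaussian mass
  y <- c(rnorm(9500), sample(c(-10, 10), 500, replace = TRUE))
  fdy <- flux_distribution(y)
  expect_gte(fdy$excess_tail_fraction, 10 * fdy$gaussian_expectation)
})
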