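test_that("firing rate is count over duration", {
  expect_equal(firing_rate(spike_train(seq(0.5, 359.5), 360)), 1)
  expect_equal(firing_rate(spike_train(numeric(0), 360)), 0)
  tr <- gen_poisson_train(5, 360, seed = 2)
  # Poisson 99% band around 5 Hz
  expect_lt(abs(firing_rate(tr) - 5), 2.576 * sqrt(5 / 360))
})

test_that("graph construction honors the strict threshold and undefined entries", {
  tr <- seq(0.5, 9.5)
  sm <- spike_matrix(list(tr, tr, tr), 10)
  M <- sttc_matrix(sm, 0.175)
  # force controlled off-diagonal values
  M$values[1, 2] <- M$values[2, 1] <- 0.3
  M$values[1, 3] <- M$values[3, 1] <- 0.6 # boundary: excluded by strict >
  M$values[2, 3] <- M$values[3, 2] <- 0.61
  g <- build_graph(M, sm, 0.6)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$sttc, 0.61)
  expect_equal(g$nodes$degree, c(0L, 1L, 1L))
  # undefined STTC never creates an edge, node retained and flagged
  sm2 <- spike_matrix(list(tr, numeric(0), tr), 10)
  g2 <- build_graph(sttc_matrix(sm2, 0.175), sm2, 0.6)
  expect_equal(nrow(g2$nodes), 3)
  expect_false(g2$nodes$defined[2])
  expect_equal(g2$nodes$degree[2], 0L)
  expect_error(build_graph(M, spike_matrix(list(tr, tr), 10)), "electrodes")
})

test_that("complete synchrony on a 60-electrode array gives degree 59 everywhere", {
  tr <- seq(0.25, 59.75, by = 0.5)
  sm <- spike_matrix(rep(list(tr), 60), 60)
  g <- build_graph(sttc_matrix(sm, 0.175), sm, 0.6)
  expect_true(all(g$nodes$degree == 59L))
  expect_equal(nrow(g$edges), 60 * 59 / 2)
  dd <- degree_distribution(g)
  expect_equal(sum(dd), 60)
  expect_equal(unname(dd["59"]), 60)
})

test_that("handshake identity and threshold monotonicity hold", {
  g0 <- gen_correlated_trains(12, 2, 0.5, 120, seed = 14)$spikes
  M <- sttc_matrix(g0, 0.175)
  prev_deg <- NULL
  for (thr in c(0.1, 0.3, 0.5, 0.7)) {
    g <- build_graph(M, g0, thr)
    expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
    if (!is.null(prev_deg)) expect_true(all(g$nodes$degree <= prev_deg))
    prev_deg <- g$nodes$degree
    expect_true(all(g$edges$sttc > thr))
  }
})

test_that("graph metrics and igraph export are consistent", {
  sp <- gen_correlated_trains(8, 2, 0.9, 60, seed = 4)$spikes
  g <- build_graph(sttc_matrix(sp, 0.175), sp, 0.6)
  m <- graph_metrics(g)
  expect_equal(m$n_edges, nrow(g$edges))
  expect_equal(m$mean_degree, mean(g$nodes$degree))
  expect_equal(m$edge_density, nrow(g$edges) / choose(8, 2))
  skip_if_not_installed("igraph")
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), 8)
  expect_equal(igraph::ecount(ig), nrow(g$edges))
})
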