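test_that("randomization preserves counts, window and validity in every scheme", {
  set.seed(1)
  sm <- spike_matrix(list(sort(runif(50, 0, 60)), numeric(0),
                          sort(runif(200, 0, 60))), 60)
  for (scheme in c("uniform", "isi_shuffle", "jitter")) {
    surr <- randomize_spike_matrix(sm, seed = 3, scheme = scheme)
    expect_identical(lengths(surr$trains), lengths(sm$trains))
    expect_identical(surr$electrode_ids, sm$electrode_ids)
    for (tt in surr$trains) {
      expect_true(all(tt >= 0 & tt < 60))
      if (length(tt) > 1) expect_true(all(diff(tt) > 0))
    }
  }
  # deterministic given seed
  expect_identical(randomize_spike_matrix(sm, seed = 3),
                   randomize_spike_matrix(sm, seed = 3))
  expect_false(identical(randomize_spike_matrix(sm, seed = 3)$trains[[1]],
                         randomize_spike_matrix(sm, seed = 4)$trains[[1]]))
})

test_that("randomization destroys synchrony of perfectly correlated trains", {
  g <- gen_correlated_trains(2, 2, 1, 360, seed = 6)$spikes
  expect_equal(sttc_pair(g[[1]], g[[2]], 0.175), 1)
  vals <- vapply(1:100, function(s) {
    surr <- randomize_spike_matrix(g, seed = s)
    sttc_pair(surr[[1]], surr[[2]], 0.175)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("null ensemble is reproducible and records every surrogate", {
  sm <- gen_correlated_trains(6, 2, 0.8, 60, seed = 2)$spikes
  cfg <- mea_config(n_surrogates = 7, seed = 99)
  e1 <- build_null_ensemble(sm, cfg)
  e2 <- build_null_ensemble(sm, cfg)
  expect_identical(e1$per_surrogate, e2$per_surrogate)
  expect_equal(nrow(e1$per_surrogate), 7)
  expect_equal(rowSums(e1$degree_dists), rep(6, 7), ignore_attr = TRUE)
})

test_that("exceedance and KS follow their defining formulas", {
  sm <- spike_matrix(rep(list(seq(0.5, 59.5)), 3), 60)
  g <- build_graph(sttc_matrix(sm, 0.175), sm, 0.6) # complete triangle
  # hand-built ensemble whose surrogates all equal the observed graph
  ens <- structure(list(
    n_surrogates = 10L, seed = 1L, scheme = "uniform",
    per_surrogate = data.frame(mean_degree = rep(2, 10), n_edges = rep(3L, 10)),
    degree_dists = matrix(rep(c(0L, 0L, 3L), each = 10), nrow = 10,
                          dimnames = list(NULL, 0:2)),
    observed = list(graph = g, mean_degree = 2, n_edges = 3L)
  ), class = "mea_null_ensemble")
  cmp <- compare_to_null(g, ens)
  expect_equal(cmp$exceedance_mean_degree, 1)
  expect_equal(cmp$ks_degree, 0)
  # observed above all surrogates -> add-one exceedance 1/(n+1)
  ens$per_surrogate$mean_degree <- rep(0, 10)
  ens$per_surrogate$n_edges <- rep(0L, 10)
  cmp2 <- compare_to_null(g, ens)
  expect_equal(cmp2$exceedance_mean_degree, 1 / 11)
  expect_equal(cmp2$exceedance_n_edges, 1 / 11)
})

test_that("a planted correlated group is flagged against the null ensemble", {
  planted <- gen_correlated_trains(5, 2, 0.9, 120, seed = 17)$spikes$trains
  indep <- lapply(1:10, function(i) gen_poisson_train(2, 120, seed = 500 + i)$times)
  sm <- spike_matrix(c(planted, indep), 120)
  ens <- build_null_ensemble(sm, mea_config(n_surrogates = 30, seed = 77))
  expect_equal(ens$comparison$exceedance_mean_degree, 1 / 31)
  expect_gt(ens$comparison$ks_degree, 0)
  # planted group members hold the highest degrees
  deg <- ens$observed$graph$nodes$degree
  expect_true(min(deg[1:5]) > max(deg[6:15]))
})
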