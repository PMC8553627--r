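test_that("tiled fraction handles closed forms, clipping and overlap", {
  expect_identical(tiled_fraction(spike_train(numeric(0), 10), 1), 0)
  # single mid-window spike, no clipping: 2*dt / T
  expect_equal(tiled_fraction(spike_train(5, 10), 1), 0.2)
  # worked case: tiles [0,2] u [4,6] (left tile clipped at 0)
  expect_equal(tiled_fraction(spike_train(c(1, 5), 10), 1), 0.4)
  # full overlap collapses to one tile
  expect_equal(tiled_fraction(spike_train(c(4.9, 5, 5.1), 10), 1),
               oracle_tiled_fraction(c(4.9, 5, 5.1), 1, 10))
  # clipping at both edges
  expect_equal(tiled_fraction(spike_train(c(0.1, 9.9), 10), 1),
               oracle_tiled_fraction(c(0.1, 9.9), 1, 10))
})

test_that("coincident fraction counts spikes near any partner spike", {
  a <- spike_train(c(1, 5), 10)
  b <- spike_train(c(1.2, 8), 10)
  expect_equal(coincident_fraction(a, b, 1), 0.5)
  expect_equal(coincident_fraction(a, a, 1), 1)
  expect_equal(coincident_fraction(a, spike_train(numeric(0), 10), 1), 0)
  expect_true(is.na(coincident_fraction(spike_train(numeric(0), 10), b, 1)))
  # window boundary is inclusive
  expect_equal(coincident_fraction(spike_train(2, 10), spike_train(3, 10), 1), 1)
})

test_that("sttc_pair reproduces the worked example and analytic limits", {
  a <- spike_train(c(1, 5), 10)
  b <- spike_train(c(1.2, 8), 10)
  # T_A = T_B = 0.4, P_A = P_B = 0.5 -> 0.5 * (0.1/0.8 + 0.1/0.8)
  expect_equal(sttc_pair(a, b, 1), 0.125)
  expect_equal(sttc_pair(a, a, 1), 1)
  expect_true(is.na(sttc_pair(spike_train(numeric(0), 10), b, 1)))
  expect_true(is.na(sttc_pair(b, spike_train(numeric(0), 10), 1)))
  expect_error(sttc_pair(a, spike_train(1, 20), 1), "duration")
})

test_that("sweep implementation agrees exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:300) {
    dur <- runif(1, 5, 20)
    dt <- runif(1, 0.05, dur / 3)
    a <- random_times(sample(0:25, 1), dur)
    b <- random_times(sample(0:25, 1), dur)
    got <- sttcnet:::.sttc_pair(a, b, dt, dur)
    want <- oracle_sttc(a, b, dt, dur)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("STTC is symmetric and bounded on random pairs", {
  set.seed(202)
  for (rep in 1:100) {
    dur <- 30
    dt <- runif(1, 0.05, 2)
    a <- spike_train(random_times(sample(1:40, 1), dur), dur)
    b <- spike_train(random_times(sample(1:40, 1), dur), dur)
    v1 <- sttc_pair(a, b, dt)
    v2 <- sttc_pair(b, a, dt)
    expect_identical(v1, v2)
    # NA is the undefined marker (degenerate denominator); defined values
    # must respect the bounds
    if (!is.na(v1)) expect_true(v1 >= -1 && v1 <= 1)
  }
})

test_that("sttc_matrix fills symmetrically and matches the pairwise loop", {
  # identical trains: all off-diagonal entries 1
  tr <- seq(0.5, 9.5, by = 1)
  sm <- spike_matrix(list(tr, tr, tr), 10)
  m <- sttc_matrix(sm, 0.175)$values
  expect_true(all(m == 1))

  g <- gen_correlated_trains(10, 2, 0.5, 60, seed = 11)$spikes
  M <- sttc_matrix(g, 0.175)
  expect_identical(M$values, t(M$values))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_identical(M$values[i, j], sttc_pair(g[[i]], g[[j]], 0.175))
    }
  }
})

test_that("empty trains yield undefined rows/diagonal, never zero", {
  sm <- spike_matrix(list(c(1, 5), numeric(0), c(2, 7)), 10)
  m <- sttc_matrix(sm, 0.5)$values
  expect_true(is.na(m[2, 2]))
  expect_true(all(is.na(m[2, c(1, 3)])))
  expect_true(all(is.na(m[c(1, 3), 2])))
  expect_equal(m[1, 1], 1)
})
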