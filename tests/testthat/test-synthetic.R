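test_that("Poisson generator is seeded, validated and has the right rate", {
  expect_length(gen_poisson_train(0, 100, seed = 1)$times, 0)
  expect_error(gen_poisson_train(-1, 100, seed = 1), "rate_hz")
  t1 <- gen_poisson_train(3, 60, seed = 42)
  t2 <- gen_poisson_train(3, 60, seed = 42)
  expect_identical(t1$times, t2$times)
  expect_false(identical(t1$times, gen_poisson_train(3, 60, seed = 43)$times))
  # empirical mean count across seeds within the 99% normal band around
  # rate * T (Poisson count oracle)
  n_seeds <- 300
  counts <- vapply(seq_len(n_seeds),
                   function(s) length(gen_poisson_train(5, 360, seed = s)$times),
                   numeric(1))
  mu <- 5 * 360
  expect_lt(abs(mean(counts) - mu), 2.576 * sqrt(mu / n_seeds))
})

test_that("MIP trains are identical copies at c = 1 and validated", {
  g <- gen_correlated_trains(6, 2, 1, 120, seed = 5)
  expect_true(all(vapply(g$spikes$trains, identical, logical(1),
                         g$spikes$trains[[1]])))
  expect_error(gen_correlated_trains(4, 2, 1.2, 60, seed = 1), "\\[0, 1\\]")
  expect_error(gen_correlated_trains(1, 2, 0.5, 60, seed = 1), "n_trains")
  expect_equal(g$ground_truth$injected_correlation, 1)
})

test_that("MIP per-train rate converges to the target rate", {
  # relative error < 5% averaged over 50 seeds at T = 360 s, rate 2 Hz
  rates <- vapply(1:50, function(s) {
    g <- gen_correlated_trains(2, 2, 0.5, 360, seed = 1000 + s)
    mean(lengths(g$spikes$trains)) / 360
  }, numeric(1))
  expect_lt(abs(mean(rates) - 2) / 2, 0.05)
})

test_that("mean pairwise STTC increases with the MIP synchrony parameter", {
  cs <- c(0, 0.3, 0.7, 1)
  means <- vapply(cs, function(cc) {
    mean(vapply(1:25, function(s) {
      g <- gen_correlated_trains(2, 2, cc, 120, seed = 7000 + s)
      sttc_pair(g$spikes[[1]], g$spikes[[2]], 0.175)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(abs(means[1]), 0.03) # independence at c = 0
})

test_that("adding a train does not perturb existing trains", {
  g5 <- gen_correlated_trains(5, 2, 0.4, 60, seed = 9)
  g8 <- gen_correlated_trains(8, 2, 0.4, 60, seed = 9)
  for (i in 1:5) {
    expect_identical(g5$spikes$trains[[i]], g8$spikes$trains[[i]])
  }
})

test_that("synth_raw stamps the template exactly in the noiseless case", {
  fs <- 25000
  w <- biphasic_waveform(fs, amplitude = 7)
  sm <- spike_matrix(list(1.0), duration_s = 2)
  out <- synth_raw(sm, fs, w, noise_sd = 0, seed = 1)
  sig <- out$recording$signal[1, ]
  start <- round(1.0 * fs) + 1
  expect_identical(sig[start:(start + length(w) - 1)], w)
  expect_true(all(sig[-(start:(start + length(w) - 1))] == 0))
  # ground truth conserved verbatim
  expect_identical(out$ground_truth$true_spike_times[[1]], sm$trains[[1]])
})

test_that("synth_raw noise level and validation behave as specified", {
  fs <- 25000
  sm <- spike_matrix(list(numeric(0)), duration_s = 8) # 2e5 samples, no spikes
  out <- synth_raw(sm, fs, biphasic_waveform(fs), noise_sd = 1.5, seed = 3)
  expect_lt(abs(sd(out$recording$signal[1, ]) - 1.5) / 1.5, 0.02)
  expect_error(
    synth_raw(spike_matrix(list(numeric(0)), 0.0004), fs,
              biphasic_waveform(fs), 1, seed = 1),
    "longer"
  )
})

test_that("a large low-frequency component is rejected by the bandpass before detection", {
  fs <- 25000
  set.seed(31)
  truth <- sort(runif(30, 0.2, 4.8))
  truth <- truth[c(TRUE, diff(truth) > 0.03)]
  sm <- spike_matrix(list(truth), duration_s = 5)
  w <- biphasic_waveform(fs, amplitude = 10)
  cfg <- mea_config(threshold_k = 5)
  base <- synth_raw(sm, fs, w, noise_sd = 1, seed = 8)
  lfp <- synth_raw(sm, fs, w, noise_sd = 1, seed = 8,
                   lfp_amplitude = 10, lfp_freq_hz = 2)
  t_base <- detect_recording(base$recording, cfg)$spikes$trains[[1]]
  t_lfp <- detect_recording(lfp$recording, cfg)$spikes$trains[[1]]
  m <- match_spikes(t_lfp, t_base, tol_s = 5e-4)
  expect_gte(m$recall, 0.99)
})
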