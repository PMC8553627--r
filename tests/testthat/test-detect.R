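test_that("bandpass rejects DC and out-of-band sinusoids, passes the band", {
  fs <- 25000
  n <- fs # 1 s
  t <- (seq_len(n) - 1) / fs
  core <- 2000:(n - 2000) # away from edge transients

  dc <- bandpass(rep(1, n), sampling_rate_hz = fs)
  expect_lt(max(abs(dc[core])), 1e-6)

  # amplitude oracle: the designed transfer function's squared magnitude
  # (zero-phase application doubles the attenuation)
  for (f0 in c(50, 3000)) {
    x <- sin(2 * pi * f0 * t)
    y <- bandpass(x, sampling_rate_hz = fs)
    amp <- sqrt(2) * sd(y[core])
    want <- bandpass_response(f0, sampling_rate_hz = fs)
    expect_lt(abs(amp - want), max(0.01 * want, 1e-3))
  }
  # 50 Hz is far below the 600 Hz corner: essentially annihilated
  y50 <- bandpass(sin(2 * pi * 50 * t), sampling_rate_hz = fs)
  expect_lt(max(abs(y50[core])), 1e-3)
})

test_that("bandpass refuses band edges at or above Nyquist", {
  rec <- mea_recording(matrix(rnorm(1000), nrow = 1), 10000)
  expect_error(bandpass(rec, 600, 8000), "Nyquist")
  expect_error(bandpass(rnorm(100), 600, 500, sampling_rate_hz = 25000),
               "band_low_hz")
})

test_that("noise estimators: robust tracks sigma under spikes, plain inflates", {
  set.seed(77)
  x <- rnorm(1e6)
  expect_lt(abs(estimate_noise(x, "robust") - 1), 0.01)
  expect_equal(estimate_noise(rep(0, 100)), 0)
  # spikes occupying < 1% of samples at 10 sigma
  xs <- x
  idx <- seq(1, 1e6, by = 150)
  xs[idx] <- xs[idx] - 10
  expect_lt(abs(estimate_noise(xs, "robust") - 1), 0.05)
  expect_gt(estimate_noise(xs, "plain"), estimate_noise(xs, "robust") + 0.1)
})

test_that("detector contracts: empty input, refractory validation, rescale invariance", {
  fs <- 25000
  expect_length(detect_spikes(rep(0, 1000), 0, sampling_rate_hz = fs)$times, 0)
  expect_error(detect_spikes(rnorm(100), 1, refractory_ms = 0.01,
                             sampling_rate_hz = fs), "refractory")
  # uniform rescaling of signal+noise leaves spike times identical
  set.seed(5)
  sm <- spike_matrix(list(sort(runif(20, 0.1, 1.9))), 2)
  rec <- synth_raw(sm, fs, biphasic_waveform(fs, 8), 1, seed = 4)$recording
  ch <- bandpass(rec)$signal[1, ]
  t1 <- detect_spikes(ch, estimate_noise(ch), sampling_rate_hz = fs)$times
  t2 <- detect_spikes(5 * ch, estimate_noise(5 * ch), sampling_rate_hz = fs)$times
  expect_identical(t1, t2)
})

test_that("refractory rule merges close events and holds on all outputs", {
  fs <- 25000
  # two spikes 1.0 ms apart (< 1.5 ms refractory) -> one detection
  sm <- spike_matrix(list(c(0.5, 0.501)), duration_s = 1)
  rec <- synth_raw(sm, fs, biphasic_waveform(fs, 10), noise_sd = 0, seed = 1)$recording
  tr <- detect_spikes(rec$signal[1, ], sigma = 1, threshold_k = 3,
                      sampling_rate_hz = fs)
  expect_length(tr$times, 1)
  # refractory invariant on a noisy channel at the default threshold
  noisy <- synth_raw(sm, fs, biphasic_waveform(fs, 10), noise_sd = 1,
                     seed = 2)$recording
  det <- detect_recording(noisy, mea_config())
  isi <- diff(det$spikes$trains[[1]])
  expect_true(all(isi >= 1.5e-3 - 1e-12))
})

test_that("false-positive rate on pure noise decreases monotonically in k", {
  fs <- 25000
  x <- sttcnet:::with_seed(12, rnorm(fs * 10))
  xf <- bandpass(x, sampling_rate_hz = fs)
  sg <- estimate_noise(xf)
  fp <- vapply(c(3, 4, 5), function(k) {
    length(detect_spikes(xf, sg, threshold_k = k, sampling_rate_hz = fs)$times)
  }, numeric(1))
  expect_true(all(diff(fp) < 0))
  expect_equal(fp[3], 0)
})

test_that("injected high-SNR spikes are recovered with sub-ms timing", {
  fs <- 25000
  dur <- 10
  set.seed(9)
  truth <- 0.05 + cumsum(0.021 + rexp(100, rate = 15)) # >= 21 ms apart
  stopifnot(max(truth) < dur - 0.05)
  sm <- spike_matrix(list(truth), duration_s = dur)
  rec <- synth_raw(sm, fs, biphasic_waveform(fs, 10), noise_sd = 1,
                   seed = 21)$recording
  det <- detect_recording(rec, mea_config(threshold_k = 5))
  got <- det$spikes$trains[[1]]
  m <- match_spikes(got, truth, tol_s = 5e-4)
  expect_gte(m$recall, 0.99)
  expect_lte(m$n_extra, 0.1 * dur)
})

test_that("end-to-end firing-rate recovery at SNR 8 is within 5%", {
  fs <- 25000
  dur <- 30
  trains <- lapply(1:3, function(i) {
    gen_poisson_train(3, dur, seed = 300 + i)$times
  })
  sm <- spike_matrix(trains, dur)
  rec <- synth_raw(sm, fs, biphasic_waveform(fs, 8), noise_sd = 1,
                   seed = 31)$recording
  det <- detect_recording(rec, mea_config(threshold_k = 5))
  got <- lengths(det$spikes$trains) / dur
  want <- lengths(sm$trains) / dur
  expect_true(all(abs(got - want) / want < 0.05))
})
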