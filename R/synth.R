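#' Homogeneous Poisson spike train
#'
#' Draws one realization of a homogeneous Poisson process on
#' `[0, duration_s)`: the spike count is Poisson with mean
#' `rate_hz * duration_s` and spike times are i.i.d. uniform, sorted.
#' A pure function of its arguments including `seed`.
#'
#' @param rate_hz Target firing rate (>= 0).
#' @param duration_s Recording length in seconds.
#' @param seed Integer seed.
#' @return A [spike_train()].
#' @examples
#' tr <- gen_poisson_train(2, 360, seed = 1)
#' firing_rate(tr)
#' @export
gen_poisson_train <- function(rate_hz, duration_s, seed) {
  if (!is_scalar_num(rate_hz) || rate_hz < 0) {
    stop_validation("`rate_hz` must be >= 0")
  }
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stop_validation("`duration_s` must be > 0")
  }
  times <- with_seed(seed, {
    n <- stats::rpois(1L, rate_hz * duration_s)
    sort(stats::runif(n, 0, duration_s))
  })
  times <- times[times < duration_s]
  spike_train(unique(times), duration_s)
}

#' Correlated spike trains (multiple-interaction process)
#'
#' Generates `n_trains` spike trains with controllable pairwise synchrony
#' via the multiple-interaction process (MIP): a mother Poisson train of
#' rate `rate_hz / c` is drawn, and each mother spike is copied into each
#' child train independently with probability `c`. Every child is then a
#' Poisson train of expected rate `rate_hz`, and the pairwise spike-count
#' correlation between children is approximately `c`. `c = 0` falls back to
#' independent Poisson trains (no mother process, no division by zero).
#' Optional Gaussian timing jitter can be added to each copied spike.
#'
#' @param n_trains Number of child trains (>= 2).
#' @param rate_hz Expected rate of each child train (> 0).
#' @param c Synchrony parameter in `[0, 1]`; at 1 all children are copies
#'   of the mother train.
#' @param duration_s Recording length in seconds.
#' @param seed Integer root seed; each child uses a derived substream, so
#'   train `i` is unchanged when `n_trains` grows.
#' @param jitter_sd_s Standard deviation of per-copy timing jitter in
#'   seconds (default 0 = exact coincidences).
#' @return A list with components `spikes` (a [spike_matrix()]) and
#'   `ground_truth` (class `mea_ground_truth`: true times, target rate,
#'   injected correlation, seed).
#' @examples
#' g <- gen_correlated_trains(5, rate_hz = 2, c = 0.5, duration_s = 60, seed = 1)
#' g$spikes
#' @export
gen_correlated_trains <- function(n_trains, rate_hz, c, duration_s, seed,
                                  jitter_sd_s = 0) {
  if (!is_count(n_trains, min = 2)) stop_validation("`n_trains` must be an integer >= 2")
  if (!is_scalar_num(rate_hz) || rate_hz <= 0) stop_validation("`rate_hz` must be > 0")
  if (!is_scalar_num(c) || c < 0 || c > 1) stop_validation("`c` must lie in [0, 1]")
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stop_validation("`duration_s` must be > 0")
  }
  if (c == 0) {
    trains <- lapply(seq_len(n_trains), function(i) {
      gen_poisson_train(rate_hz, duration_s, substream_seed(seed, i))$times
    })
  } else {
    mother <- gen_poisson_train(rate_hz / c, duration_s,
                                substream_seed(seed, 0L))$times
    trains <- lapply(seq_len(n_trains), function(i) {
      with_seed(substream_seed(seed, i), {
        keep <- stats::runif(length(mother)) < c
        t_i <- mother[keep]
        if (jitter_sd_s > 0 && length(t_i)) {
          t_i <- t_i + stats::rnorm(length(t_i), 0, jitter_sd_s)
          t_i <- t_i[t_i >= 0 & t_i < duration_s]
        }
        sort(unique(t_i))
      })
    })
  }
  spikes <- spike_matrix(trains, duration_s)
  gt <- structure(list(true_spike_times = trains,
                       target_rate_hz = rep(rate_hz, n_trains),
                       injected_correlation = c,
                       waveform = NULL, noise_sd = NULL,
                       seed = as.integer(seed)),
                  class = "mea_ground_truth")
  list(spikes = spikes, ground_truth = gt)
}

#' Biphasic extracellular spike template
#'
#' A simple biphasic waveform (sharp negative peak followed by a slower
#' positive rebound), 1 ms long by default, matching the negative-polarity
#' default of the detector. The negative peak sits a quarter of the way
#' into the template, so a spike stamped at time `t` has its detected
#' extremum about 0.25 ms after `t`.
#'
#' @param sampling_rate_hz Sampling rate used to sample the template.
#' @param amplitude Absolute amplitude of the negative peak. Expressing it
#'   as a multiple of the background `noise_sd` sets the signal-to-noise
#'   ratio of [synth_raw()].
#' @param duration_ms Total template length in milliseconds.
#' @return Numeric vector of template samples.
#' @examples
#' w <- biphasic_waveform(25000, amplitude = 8)
#' length(w) # 25 samples = 1 ms at 25 kHz
#' @export
biphasic_waveform <- function(sampling_rate_hz, amplitude = 1, duration_ms = 1) {
  n <- max(4L, round(sampling_rate_hz * duration_ms / 1000))
  t <- seq_len(n) / n
  split <- 0.5
  w <- numeric(n)
  neg <- t <= split
  w[neg] <- -amplitude * sin(pi * t[neg] / split)
  w[!neg] <- 0.4 * amplitude * sin(pi * (t[!neg] - split) / (1 - split))
  w
}

#' Synthesize a raw multichannel recording from known spike times
#'
#' Builds a channels x samples voltage matrix: per channel, white Gaussian
#' noise of standard deviation `noise_sd`, plus the waveform template added
#' starting at each true spike time (sample-aligned, truncated at the
#' window edges), plus an optional low-frequency sinusoid emulating a local
#' field potential (useful to exercise the high-pass side of the bandpass
#' filter). The input spike matrix is returned verbatim as ground truth.
#'
#' @param spikes A [spike_matrix()] of true spike times (one train per
#'   channel).
#' @param sampling_rate_hz Sampling rate; must exceed twice the upper
#'   bandpass corner if detection with default settings will follow.
#' @param waveform Sampled spike template (see [biphasic_waveform()]).
#' @param noise_sd Background noise standard deviation, same units as the
#'   waveform amplitude.
#' @param seed Integer root seed; each channel's noise uses a derived
#'   substream.
#' @param lfp_amplitude,lfp_freq_hz Amplitude and frequency of the optional
#'   sinusoidal LFP component (0 = none).
#' @return A list with components `recording` (an [mea_recording()]) and
#'   `ground_truth` (`mea_ground_truth` carrying the input spike times
#'   verbatim).
#' @examples
#' sm <- spike_matrix(list(c(0.1, 0.5), 0.3), duration_s = 1)
#' out <- synth_raw(sm, 25000, biphasic_waveform(25000, 8), noise_sd = 1, seed = 1)
#' out$recording
#' @export
synth_raw <- function(spikes, sampling_rate_hz, waveform, noise_sd, seed,
                      lfp_amplitude = 0, lfp_freq_hz = 0) {
  stopifnot(inherits(spikes, "spike_matrix"))
  if (!is_scalar_num(noise_sd) || noise_sd < 0) stop_validation("`noise_sd` must be >= 0")
  n_samp <- round(spikes$duration_s * sampling_rate_hz)
  n_chan <- length(spikes)
  if (length(waveform) > n_samp) {
    stop_validation("waveform is longer than the recording")
  }
  sig <- matrix(0, nrow = n_chan, ncol = n_samp)
  t_axis <- NULL
  if (lfp_amplitude != 0 && lfp_freq_hz > 0) {
    t_axis <- (seq_len(n_samp) - 1) / sampling_rate_hz
    lfp <- lfp_amplitude * sin(2 * pi * lfp_freq_hz * t_axis)
  }
  wlen <- length(waveform)
  for (i in seq_len(n_chan)) {
    ch <- if (noise_sd > 0) {
      with_seed(substream_seed(seed, i), stats::rnorm(n_samp, 0, noise_sd))
    } else {
      numeric(n_samp)
    }
    for (tt in spikes$trains[[i]]) {
      start <- round(tt * sampling_rate_hz) + 1L
      if (start > n_samp) next
      idx <- start:min(start + wlen - 1L, n_samp)
      ch[idx] <- ch[idx] + waveform[seq_along(idx)]
    }
    if (!is.null(t_axis)) ch <- ch + lfp
    sig[i, ] <- ch
  }
  rec <- mea_recording(sig, sampling_rate_hz)
  gt <- structure(list(true_spike_times = spikes$trains,
                       target_rate_hz = lengths(spikes$trains) / spikes$duration_s,
                       injected_correlation = NULL,
                       waveform = waveform, noise_sd = noise_sd,
                       seed = as.integer(seed)),
                  class = "mea_ground_truth")
  list(recording = rec, ground_truth = gt)
}
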