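---
title: "Inferring functional connectivity from MEA spike trains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional connectivity from MEA spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sttcnet)
```

# The analysis chain

`sttcnet` turns spontaneous extracellular voltage recorded on a
multielectrode array (MEA) — typically a 60-electrode grid with 200-µm
pitch under an organoid slice or other neural preparation — into a
functional connectivity network. The chain has four stages, all governed
by one `mea_config()`:

1. **Filtering.** The raw signal is bandpass-filtered with a third-order
   Butterworth design, 600–8,000 Hz, applied zero-phase
   (forward–backward). This isolates the spike band: local field
   potentials and electrode drift sit far below 600 Hz, amplifier noise
   extends above 8 kHz.
2. **Spike detection.** Per channel, the background noise standard
   deviation σ is estimated on the filtered trace and events are detected
   where the signal exceeds *k*·σ (default *k* = 3) in the configured
   polarity, with a 1.5-ms refractory period after each accepted event.
3. **Connectivity.** Every electrode pair is scored with the spike-time
   tiling coefficient (STTC) at a synchronicity window of Δt = 175 ms.
4. **Graph and null model.** Edges are drawn for STTC strictly greater
   than 0.6, weighted by the STTC; each node carries its binary degree and
   firing rate (spikes/s). The observed graph is compared against an
   ensemble of surrogate graphs built from temporally randomized spike
   trains with the identical per-electrode spike counts, hence an
   identical firing-rate distribution.

`mea_network()` runs the whole chain and returns a fitted-model-style
object with `print`, `summary`, `coef`, `plot` and `simulate` methods.

# The spike-time tiling coefficient

For trains A and B on a recording of length T, with a half-window Δt:

- $T_A$ — the fraction of the recording lying within ±Δt of *any* spike
  of A. Tiles are clipped to the recording window $[0, T)$ and merged
  where they overlap: $T_A$ is the measure of a union of intervals, not a
  sum, so it cannot exceed 1.
- $P_A$ — the proportion of A's spikes lying within ±Δt of at least one
  spike of B (boundary inclusive).

$$\mathrm{STTC} = \frac{1}{2}\left(
  \frac{P_A - T_B}{1 - P_A T_B} + \frac{P_B - T_A}{1 - P_B T_A}\right)$$

Each term compares the fraction of one train's spikes that fall near the
other train's spikes ($P$) with the fraction expected by chance if spikes
were placed blindly ($T$). This makes the coefficient approximately
invariant to the firing rates of the two trains under independence — the
property that makes it usable across electrodes whose rates differ by
orders of magnitude, and the reason it is preferred over raw coincidence
counts. It is symmetric and bounded in $[-1, 1]$, and a non-empty train
with tiled fraction below 1 scores exactly 1 against itself.

```{r sttc-example}
a <- spike_train(c(1, 5), 10)
b <- spike_train(c(1.2, 8), 10)
sttc_pair(a, b, dt_s = 1) # T_A = T_B = 0.4, P_A = P_B = 0.5 -> 0.125
```

**Undefined values.** An empty train has no defined $P$, and a pair with
$P_A T_B = 1$ (possible when dense trains tile the whole recording) has
no defined ratio. Both yield `NA`, never 0: zero is a meaningful STTC
("uncorrelated") and must not be conflated with "not computable". Graph
construction treats `NA` as "no edge" while keeping the electrode in the
node table, so the array size stays fixed.

**Implementation and its oracle.** The production path computes $T$ by a
vectorized merge over the sorted tile boundaries and $P$ by binary search
(`findInterval`) — $O(n \log n)$ per pair, with per-train tile fractions
reused across the whole matrix. Correctness is anchored to an independent
brute-force oracle (explicit interval merging, exhaustive pairwise
coincidence checks) that the test suite runs against 1,000+ random train
pairs, demanding agreement to $10^{-12}$.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `band_low_hz`, `band_high_hz` | 600, 8000 | Hz | spike band; LFP and drift rejected below, amplifier noise above |
| `filter_order` | 3 | — | Butterworth prototype order; applied twice (zero-phase) |
| `threshold_k` | 3 | ×σ | detection threshold in noise SDs |
| `refractory_ms` | 1.5 | ms | minimum interval between accepted events on one channel |
| `sttc_dt_ms` | 175 | ms | STTC synchronicity half-window |
| `edge_threshold` | 0.6 | — | STTC a pair must *strictly* exceed to become an edge |
| `n_surrogates` | 100 | — | size of the null ensemble |
| `noise_estimator` | `"robust"` | — | `median(|x|)/0.6745` vs plain SD |
| `polarity` | `"negative"` | — | extracellular somatic spikes are predominantly negative-going |

Decisions behind the less obvious entries:

- **Zero-phase filtering.** A causal filter would delay spikes by the
  group delay (hundreds of µs near the low corner). Forward–backward
  application cancels the phase entirely; the cost — squared magnitude
  response — is documented and is what the filter tests check against.
  For a 175-ms coincidence statistic a sub-ms lag would be immaterial
  anyway, but zero-phase keeps timing tests exact.
- **Robust noise estimator.** The plain SD includes the spikes
  themselves, inflating the threshold on active channels. The
  median-based estimator is within 1% of the true σ with spikes occupying
  a few percent of samples; both are available because "SD of background
  noise" admits either reading.
- **Event time = excursion extremum**, not first threshold crossing: the
  crossing point jitters with noise amplitude, the peak does not.
- **Strict edge inequality.** An STTC exactly at the threshold is not an
  edge; boundary behavior is pinned by a test.
- **Noise-estimation edge guard.** The first and last ten time constants
  of the high-pass corner are excluded from noise estimation (filtfilt
  start-up transients), but not from detection.

# Detection thresholds and false positives

A threshold rule has an irreducible false-positive rate set by the noise
bandwidth. For stationary Gaussian noise in the 600–8,000 Hz band, the
expected rate of excursions beyond $k\sigma$ follows the level-crossing
(Rice) rate $\nu_0 e^{-k^2/2}$ with $\nu_0 \approx 4.8$ kHz — roughly
50 events/s at $k = 3$, 1 Hz at $k = 4$, and 0.02 Hz at $k = 5$. The
package's validation therefore splits naturally:

- properties that hold at the default $k = 3$ (refractory invariant,
  monotone decrease of the false-positive rate in $k$, rescale
  invariance) are tested there;
- quantitative recovery claims (≥ 99% recall at ±0.5 ms, false positives
  below 0.1 Hz, firing-rate recovery within 5% at SNR ≥ 8) are tested at
  $k = 5$, where the crossing rate makes them achievable. Below
  $k \approx 4.7$ no detector obeying the stated rule can keep noise
  events under 0.1 Hz on this bandwidth, and the noise events' refractory
  windows also clip a few percent of true spikes.

Real recordings sit between these regimes: channel noise is not exactly
Gaussian and practitioners routinely accept that a 3σ threshold trades
sensitivity for purity.

# The synthetic-data module

Because validation needs ground truth, the package generates its own:

- `gen_poisson_train()` — homogeneous Poisson trains, the stand-in for
  spontaneous uncorrelated activity.
- `gen_correlated_trains()` — the multiple-interaction process (MIP): a
  mother Poisson train at rate $r/c$, each spike copied into each child
  independently with probability $c$. Children are Poisson at rate $r$
  with pairwise count correlation ≈ $c$ — a single interpretable knob for
  synchrony, which is why MIP was chosen over single-interaction schemes.
  $c = 0$ falls back to independent trains exactly. The ensemble-mean
  STTC increases strictly in $c$, which the tests exploit as a
  monotonicity oracle.
- `synth_raw()` — white Gaussian noise per channel plus a biphasic 1-ms
  template (negative peak, positive rebound; amplitude in multiples of
  the noise SD, i.e. the SNR) stamped at each true spike time, with an
  optional low-frequency sinusoid to exercise the high-pass corner.

Every generator is a pure function of its arguments including the seed;
per-train and per-channel substreams derive from the root seed, so adding
an electrode never perturbs the others.

The default fixture emulates the target preparation's scale: 60
electrodes, 360-s windows, per-electrode rates in the 0.1–5 Hz range.
These are test fixtures, not biological claims. What the generator does
**not** emulate — and hence what green tests do not certify on real
data — includes bursting and up/down-state dynamics, spike-waveform
variability and cross-electrode waveform propagation, overlapping spikes
from multiple units on one electrode, non-Gaussian or nonstationary
noise, and electrode artifacts. The pipeline performs no spike sorting;
an "electrode train" is a multi-unit train.

# The surrogate null model

"Temporally randomized spike trains with equivalent spike-rate
distribution" is realized, by default, as the weakest-assumption scheme
that provably preserves the rate distribution: each electrode's $n_i$
spike times are redrawn uniformly on $[0, T)$ with the count preserved
exactly. Two stricter schemes are available via `scheme =` — inter-spike
interval shuffling (preserves each train's ISI distribution) and spike
jitter (preserves slow rate structure) — since the choice of granularity
is genuinely open; the uniform scheme is the default because it destroys
all temporal structure and makes the null maximally conservative about
what counts as "synchrony".

Comparisons report numbers, not verdicts: the empirical exceedance
fraction $(1 + \#\{\text{surrogates} \ge \text{observed}\})/(n + 1)$ for
mean degree and edge count (the add-one convention avoids zero
p-values), and the two-sample Kolmogorov–Smirnov statistic between
observed and pooled surrogate degree distributions.

A calibration subtlety: at the analysis threshold of 0.6 the null graph
is empty in both observed and surrogate data, so the exceedance is
degenerately 1 and says nothing. The calibration tests (null inputs
should *not* be flagged) therefore run at a reduced problem size with the
edge threshold placed near the upper tail of the null STTC distribution
(0.06 for 2-Hz trains on 120-s windows, where the null STTC SD is ≈
0.04), the regime in which chance edges occur and the exceedance can
spread over the unit interval. The planted-structure power tests use the
full 0.6 threshold.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at sizes chosen to make the statistics decisive while keeping a full run
in minutes on one CPU: 1,000 random train pairs for oracle equivalence;
200 independent-pair seeds per rate for the independence null (mean STTC
within ±0.02 of 0 at 0.5, 2 and 10 Hz); 100 surrogates for the planted
10-of-60 power test on 360-s trains; 50 replicate experiments for null
calibration; 25-kHz, 10–30-s multichannel recordings for detection. Spike
times are 64-bit doubles in seconds on a half-open window $[0, T)$;
electrode IDs are 0-based; reports contain no timestamps so reruns are
byte-identical.

# Known limitations

- STTC is computed on whole recordings; sub-windowed or lag-resolved
  profiles are out of scope.
- No spike sorting, artifact rejection or bad-channel heuristics beyond
  the threshold rule.
- The binary degree is reported (edges above threshold); weighted degree
  can be recovered from the edge list if wanted.
- Group-level statistics across biological conditions (ANOVA on firing
  rates and the like) are deliberately left to standard tools; the
  package stops at per-recording networks and their null comparisons.
- Proprietary vendor file dialects are not parsed; recordings enter
  through the documented flat-binary + JSON container or as spike-time
  tables.
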