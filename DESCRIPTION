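Package: sttcnet
Title: Functional Connectivity Networks from Multielectrode Array Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers functional connectivity networks from extracellular
    multielectrode array (MEA) recordings of spontaneous neural activity,
    such as organoid slice cultures. Provides Butterworth bandpass
    filtering, noise-relative threshold spike detection with a refractory
    period, the spike-time tiling coefficient (STTC) as a rate-insensitive
    pairwise synchrony statistic, thresholded graph construction with
    per-electrode degree and firing rate, and surrogate-data null models
    based on temporally randomized spike trains that preserve each
    electrode's spike count. A synthetic-data module generates Poisson and
    correlated spike trains (multiple-interaction process) and raw
    multichannel recordings with known ground truth, so every stage of the
    pipeline can be validated against simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
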