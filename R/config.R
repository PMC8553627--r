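#' Analysis configuration
#'
#' Bundles every tunable parameter of the MEA analysis chain. The defaults
#' are the standard settings for spontaneous-activity recordings from
#' organoid slices on a 60-electrode array: third-order Butterworth bandpass
#' 600--8,000 Hz, spike threshold at 3 standard deviations of the background
#' noise with a 1.5-ms refractory period, spike-time tiling coefficient with
#' a 175-ms synchronicity window, and functional edges for STTC > 0.6.
#'
#' @param band_low_hz Lower bandpass corner in Hz.
#' @param band_high_hz Upper bandpass corner in Hz; must exceed `band_low_hz`
#'   and stay below the Nyquist frequency of any recording it is applied to.
#' @param filter_order Analog prototype order of the Butterworth design.
#'   The filter is applied zero-phase (forward-backward), so the effective
#'   magnitude response is the square of this design.
#' @param threshold_k Detection threshold as a multiple of the estimated
#'   background noise standard deviation.
#' @param refractory_ms Minimum interval enforced between accepted spikes on
#'   one channel, in milliseconds.
#' @param sttc_dt_ms STTC synchronicity window (half-width) in milliseconds.
#' @param edge_threshold STTC value a pair must strictly exceed to become an
#'   edge of the connectivity graph.
#' @param n_surrogates Number of temporally randomized surrogate spike
#'   matrices in the null ensemble.
#' @param seed Integer root seed for all randomness (surrogates, simulation).
#' @param noise_estimator `"robust"` (median absolute value / 0.6745, the
#'   default -- insensitive to the spikes themselves) or `"plain"` (sample
#'   standard deviation of the whole filtered trace).
#' @param polarity Spike polarity to detect: `"negative"` (default;
#'   extracellular somatic spikes are predominantly negative-going),
#'   `"positive"`, or `"both"`.
#'
#' @return An object of class `mea_config`: a validated named list.
#' @examples
#' cfg <- mea_config()
#' cfg$sttc_dt_ms
#' @export
mea_config <- function(band_low_hz = 600, band_high_hz = 8000,
                       filter_order = 3, threshold_k = 3.0,
                       refractory_ms = 1.5, sttc_dt_ms = 175,
                       edge_threshold = 0.6, n_surrogates = 100,
                       seed = 1L,
                       noise_estimator = c("robust", "plain"),
                       polarity = c("negative", "positive", "both")) {
  noise_estimator <- match.arg(noise_estimator)
  polarity <- match.arg(polarity)
  cfg <- list(
    band_low_hz = band_low_hz, band_high_hz = band_high_hz,
    filter_order = filter_order, threshold_k = threshold_k,
    refractory_ms = refractory_ms, sttc_dt_ms = sttc_dt_ms,
    edge_threshold = edge_threshold, n_surrogates = n_surrogates,
    seed = as.integer(seed), noise_estimator = noise_estimator,
    polarity = polarity
  )
  validate_config(cfg)
}

#' Validate a configuration
#'
#' Range-checks every field of a configuration given as an `mea_config`
#' object, a plain named list (missing fields take the defaults of
#' [mea_config()]), or a path to a YAML file with the same keys. An empty
#' file or list yields the full default configuration.
#'
#' @param config An `mea_config`, a named list, or a file path.
#' @return A validated `mea_config`.
#' @examples
#' validate_config(list(sttc_dt_ms = 100))$sttc_dt_ms
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_format("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (!is.list(config)) stop_validation("config must be a list or file path")
  if (inherits(config, "mea_config")) {
    cfg <- unclass(config)
  } else {
    defaults <- formals(mea_config)
    cfg <- list(
      band_low_hz = config$band_low_hz %||% eval(defaults$band_low_hz),
      band_high_hz = config$band_high_hz %||% eval(defaults$band_high_hz),
      filter_order = config$filter_order %||% eval(defaults$filter_order),
      threshold_k = config$threshold_k %||% eval(defaults$threshold_k),
      refractory_ms = config$refractory_ms %||% eval(defaults$refractory_ms),
      sttc_dt_ms = config$sttc_dt_ms %||% eval(defaults$sttc_dt_ms),
      edge_threshold = config$edge_threshold %||% eval(defaults$edge_threshold),
      n_surrogates = config$n_surrogates %||% eval(defaults$n_surrogates),
      seed = as.integer(config$seed %||% 1L),
      noise_estimator = config$noise_estimator %||% "robust",
      polarity = config$polarity %||% "negative"
    )
    extra <- setdiff(names(config), c(names(cfg), ""))
    if (length(extra)) {
      stop_validation("unknown config field(s): ", paste(extra, collapse = ", "))
    }
  }
  chk <- function(ok, field, msg) {
    if (!ok) stop_validation("config field `", field, "` ", msg)
  }
  chk(is_scalar_num(cfg$band_low_hz) && cfg$band_low_hz > 0,
      "band_low_hz", "must be a positive number")
  chk(is_scalar_num(cfg$band_high_hz) && cfg$band_high_hz > cfg$band_low_hz,
      "band_high_hz", "must exceed band_low_hz")
  chk(is_count(cfg$filter_order, min = 1), "filter_order", "must be an integer >= 1")
  chk(is_scalar_num(cfg$threshold_k) && cfg$threshold_k > 0,
      "threshold_k", "must be > 0")
  chk(is_scalar_num(cfg$refractory_ms) && cfg$refractory_ms > 0,
      "refractory_ms", "must be > 0")
  chk(is_scalar_num(cfg$sttc_dt_ms) && cfg$sttc_dt_ms > 0,
      "sttc_dt_ms", "must be > 0")
  chk(is_scalar_num(cfg$edge_threshold) &&
        cfg$edge_threshold >= 0 && cfg$edge_threshold <= 1,
      "edge_threshold", "must lie in [0, 1]")
  chk(is_count(cfg$n_surrogates, min = 1), "n_surrogates", "must be an integer >= 1")
  chk(is_count(abs(cfg$seed)), "seed", "must be an integer")
  chk(cfg$noise_estimator %in% c("robust", "plain"),
      "noise_estimator", "must be 'robust' or 'plain'")
  chk(cfg$polarity %in% c("negative", "positive", "both"),
      "polarity", "must be 'negative', 'positive' or 'both'")
  structure(cfg, class = "mea_config")
}

#' @export
print.mea_config <- function(x, ...) {
  cat("MEA analysis configuration\n")
  cat(sprintf("  bandpass: %g-%g Hz (Butterworth order %d, zero-phase)\n",
              x$band_low_hz, x$band_high_hz, x$filter_order))
  cat(sprintf("  detection: %g x noise SD (%s), refractory %g ms, polarity %s\n",
              x$threshold_k, x$noise_estimator, x$refractory_ms, x$polarity))
  cat(sprintf("  STTC window: %g ms; edge threshold: STTC > %g\n",
              x$sttc_dt_ms, x$edge_threshold))
  cat(sprintf("  surrogates: %d (seed %d)\n", x$n_surrogates, x$seed))
  invisible(x)
}
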