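#' Spike train
#'
#' A sorted sequence of spike times on a half-open recording window
#' `[0, duration_s)`. Times are stored in seconds as doubles; the half-open
#' convention means a spike at exactly the recording length is invalid, so
#' windows tile without double counting.
#'
#' @param times Numeric vector of spike times in seconds; must be strictly
#'   increasing and lie in `[0, duration_s)`.
#' @param duration_s Positive recording length in seconds.
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(c(0.5, 1.0, 2.25), duration_s = 10)
#' @export
spike_train <- function(times = numeric(0), duration_s) {
  if (!is_scalar_num(duration_s) || duration_s <= 0) {
    stop_validation("`duration_s` must be a single positive number")
  }
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop_validation("spike times must be finite")
  }
  if (length(times) && (any(times < 0) || any(times >= duration_s))) {
    stop_validation("spike times must lie in [0, duration_s)")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop_validation("spike times must be strictly increasing")
  }
  structure(list(times = times, duration_s = as.numeric(duration_s)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g s (%.4g Hz)\n",
              length(x$times), x$duration_s, firing_rate(x)))
  invisible(x)
}

#' Spike matrix
#'
#' A collection of spike trains over a common recording window, one per
#' electrode, keyed by 0-based integer electrode IDs.
#'
#' @param trains List of numeric spike-time vectors or `spike_train`
#'   objects, one per electrode.
#' @param duration_s Common recording length in seconds.
#' @param electrode_ids Integer electrode IDs (0-based); defaults to
#'   `0:(length(trains) - 1)`.
#' @return An object of class `spike_matrix`.
#' @examples
#' spike_matrix(list(c(0.5, 1), 2, numeric(0)), duration_s = 10)
#' @export
spike_matrix <- function(trains, duration_s, electrode_ids = NULL) {
  if (!is.list(trains)) stop_validation("`trains` must be a list")
  trains <- lapply(trains, function(tr) {
    if (inherits(tr, "spike_train")) {
      if (!isTRUE(all.equal(tr$duration_s, duration_s))) {
        stop_validation("all trains must share `duration_s`")
      }
      tr$times
    } else {
      spike_train(tr, duration_s)$times
    }
  })
  n <- length(trains)
  if (n < 1L) stop_validation("need at least one train")
  electrode_ids <- electrode_ids %||% (seq_len(n) - 1L)
  electrode_ids <- as.integer(electrode_ids)
  if (length(electrode_ids) != n || anyDuplicated(electrode_ids)) {
    stop_validation("`electrode_ids` must be unique and match the train count")
  }
  names(trains) <- as.character(electrode_ids)
  structure(list(trains = trains, duration_s = as.numeric(duration_s),
                 electrode_ids = electrode_ids),
            class = "spike_matrix")
}

#' @export
print.spike_matrix <- function(x, ...) {
  counts <- lengths(x$trains)
  cat(sprintf("Spike matrix: %d electrodes over %g s\n",
              length(x$trains), x$duration_s))
  cat(sprintf("  spikes/electrode: median %g, range %d-%d; %d silent\n",
              stats::median(counts), min(counts), max(counts),
              sum(counts == 0L)))
  invisible(x)
}

#' @export
length.spike_matrix <- function(x) length(x$trains)

# Extract one train as a spike_train object.
#' @export
`[[.spike_matrix` <- function(x, i) {
  spike_train(x$trains[[i]], x$duration_s)
}

#' Mean firing rate of a spike train
#'
#' Spike count divided by the recording duration (spikes per second).
#'
#' @param train A `spike_train`, or a numeric vector of times combined with
#'   `duration_s`.
#' @param duration_s Recording length in seconds (ignored when `train` is a
#'   `spike_train`).
#' @return Firing rate in Hz.
#' @examples
#' firing_rate(spike_train(seq(0, 359), 360)) # 1 Hz
#' @export
firing_rate <- function(train, duration_s = NULL) {
  if (inherits(train, "spike_train")) {
    length(train$times) / train$duration_s
  } else {
    if (!is_scalar_num(duration_s) || duration_s <= 0) {
      stop_validation("`duration_s` must be a single positive number")
    }
    length(train) / duration_s
  }
}
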