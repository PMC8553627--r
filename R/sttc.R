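# Spike-time tiling coefficient (STTC).
#
# For trains A and B on a window of length T with synchronicity half-width
# dt:
#   T_A = fraction of [0, T) covered by the union of +-dt tiles around A's
#         spikes (tiles clipped to the window; overlaps merged, not summed)
#   P_A = proportion of A's spikes lying within +-dt of at least one B spike
# and symmetrically for B, then
#   STTC = 1/2 * [ (P_A - T_B) / (1 - P_A * T_B)
#                + (P_B - T_A) / (1 - P_B * T_A) ].
# The statistic is symmetric, lies in [-1, 1], and is approximately
# invariant to the firing rates of the two trains under independence,
# which is why it is preferred over raw coincidence counts for comparing
# electrodes with very different activity levels.
#
# Degenerate cases are NA by design, never silently 0: an empty train has
# no defined P, and a zero denominator (P_A * T_B = 1) has no defined
# ratio. 0 is a meaningful STTC value ("uncorrelated"), so it is reserved
# for actual computations.

# Internal kernels on bare sorted numeric vectors; exported wrappers add
# validation. Two-pointer-free vectorized forms, O(n log n) per pair.

.tiled_fraction <- function(times, dt_s, duration_s) {
  n <- length(times)
  if (n == 0L) return(0)
  starts <- pmax(times - dt_s, 0)
  ends <- pmin(times + dt_s, duration_s)
  # times sorted => starts and ends nondecreasing; interval i can only
  # overlap the union through the previous interval's end
  prev_end <- c(-Inf, ends[-n])
  sum(pmax(0, ends - pmax(starts, prev_end))) / duration_s
}

.coincident_count <- function(a, b, dt_s) {
  nb <- length(b)
  if (nb == 0L) return(0L)
  idx <- findInterval(a, b) # largest index with b[idx] <= a (0 if none)
  has_prev <- idx >= 1L
  prev_ok <- has_prev & (a - b[pmax(idx, 1L)] <= dt_s)
  has_next <- idx < nb
  next_ok <- has_next & (b[pmin(idx + 1L, nb)] - a <= dt_s)
  sum(prev_ok | next_ok)
}

.sttc_pair <- function(a, b, dt_s, duration_s, ta = NULL, tb = NULL) {
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  ta <- ta %||% .tiled_fraction(a, dt_s, duration_s)
  tb <- tb %||% .tiled_fraction(b, dt_s, duration_s)
  pa <- .coincident_count(a, b, dt_s) / length(a)
  pb <- .coincident_count(b, a, dt_s) / length(b)
  d1 <- 1 - pa * tb
  d2 <- 1 - pb * ta
  if (d1 == 0 || d2 == 0) return(NA_real_)
  0.5 * ((pa - tb) / d1 + (pb - ta) / d2)
}

#' Tiled time fraction of a spike train
#'
#' The fraction of the recording window `[0, T)` lying within `dt_s` of at
#' least one spike: the union (not the sum) of the per-spike tiles
#' `[t - dt_s, t + dt_s]`, clipped to the window. This is the `T` term of
#' the spike-time tiling coefficient.
#'
#' @param train A [spike_train()].
#' @param dt_s Synchronicity half-width in seconds (> 0).
#' @return A value in `[0, 1]`.
#' @examples
#' tiled_fraction(spike_train(c(1, 5), 10), dt_s = 1) # tiles [0,2] u [4,6] -> 0.4
#' @export
tiled_fraction <- function(train, dt_s) {
  stopifnot(inherits(train, "spike_train"))
  if (!is_scalar_num(dt_s) || dt_s <= 0) stop_validation("`dt_s` must be > 0")
  .tiled_fraction(train$times, dt_s, train$duration_s)
}

#' Coincident spike fraction
#'
#' The proportion of spikes in `train_a` lying within `dt_s` of at least
#' one spike of `train_b` (the `P` term of the spike-time tiling
#' coefficient). Undefined (`NA`) when `train_a` is empty; 0 when
#' `train_b` is empty.
#'
#' @param train_a,train_b [spike_train()] objects on the same window.
#' @param dt_s Synchronicity half-width in seconds.
#' @return A value in `[0, 1]`, or `NA` for an empty `train_a`.
#' @examples
#' a <- spike_train(c(1, 5), 10); b <- spike_train(c(1.2, 8), 10)
#' coincident_fraction(a, b, 1) # 0.5
#' @export
coincident_fraction <- function(train_a, train_b, dt_s) {
  stopifnot(inherits(train_a, "spike_train"), inherits(train_b, "spike_train"))
  if (!is_scalar_num(dt_s) || dt_s <= 0) stop_validation("`dt_s` must be > 0")
  if (length(train_a$times) == 0L) return(NA_real_)
  .coincident_count(train_a$times, train_b$times, dt_s) / length(train_a$times)
}

#' Spike-time tiling coefficient of a train pair
#'
#' Computes `STTC = 1/2 * [(P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 -
#' P_B T_A)]`, where `P` are coincident-spike proportions and `T` tiled
#' time fractions (see [coincident_fraction()], [tiled_fraction()]).
#' Symmetric in its arguments and bounded in `[-1, 1]`; a non-empty train
#' with tiled fraction below 1 scores exactly 1 against itself. Empty
#' trains and zero denominators yield `NA` (undefined), never 0.
#'
#' @param train_a,train_b [spike_train()] objects sharing `duration_s`.
#' @param dt_s Synchronicity half-width in seconds (0.175 for the standard
#'   175-ms window).
#' @return The STTC value, or `NA` if undefined.
#' @examples
#' a <- spike_train(c(1, 5), 10); b <- spike_train(c(1.2, 8), 10)
#' sttc_pair(a, b, dt_s = 1) # 0.125
#' @export
sttc_pair <- function(train_a, train_b, dt_s) {
  stopifnot(inherits(train_a, "spike_train"), inherits(train_b, "spike_train"))
  if (!isTRUE(all.equal(train_a$duration_s, train_b$duration_s))) {
    stop_validation("trains must share `duration_s`")
  }
  if (!is_scalar_num(dt_s) || dt_s <= 0) stop_validation("`dt_s` must be > 0")
  .sttc_pair(train_a$times, train_b$times, dt_s, train_a$duration_s)
}

#' Pairwise STTC matrix over a spike matrix
#'
#' Computes [sttc_pair()] once per unordered electrode pair and fills the
#' square matrix symmetrically. The diagonal is 1 for non-empty trains and
#' `NA` for empty ones; `NA` entries elsewhere mark undefined pairs (an
#' empty train or a degenerate denominator) and are preserved, not zeroed.
#'
#' @param spikes A [spike_matrix()].
#' @param dt_s Synchronicity half-width in seconds.
#' @return An object of class `sttc_matrix`: list with `values` (square
#'   symmetric matrix, dimnames = electrode IDs), `dt_s`, `duration_s`,
#'   `electrode_ids`.
#' @examples
#' sm <- spike_matrix(list(c(1, 5), c(1.2, 8), numeric(0)), 10)
#' sttc_matrix(sm, dt_s = 1)$values
#' @export
sttc_matrix <- function(spikes, dt_s) {
  stopifnot(inherits(spikes, "spike_matrix"))
  if (!is_scalar_num(dt_s) || dt_s <= 0) stop_validation("`dt_s` must be > 0")
  trains <- spikes$trains
  n <- length(trains)
  dur <- spikes$duration_s
  tiled <- vapply(trains, .tiled_fraction, numeric(1),
                  dt_s = dt_s, duration_s = dur)
  vals <- matrix(NA_real_, n, n,
                 dimnames = list(as.character(spikes$electrode_ids),
                                 as.character(spikes$electrode_ids)))
  diag(vals) <- ifelse(lengths(trains) > 0L, 1, NA_real_)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- .sttc_pair(trains[[i]], trains[[j]], dt_s, dur,
                        ta = tiled[i], tb = tiled[j])
        vals[i, j] <- v
        vals[j, i] <- v
      }
    }
  }
  structure(list(values = vals, dt_s = dt_s, duration_s = dur,
                 electrode_ids = spikes$electrode_ids),
            class = "sttc_matrix")
}

#' @export
print.sttc_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("STTC matrix: %d electrodes, dt = %g s\n",
              nrow(x$values), x$dt_s))
  if (length(off)) {
    cat(sprintf("  off-diagonal: mean %.4f, max %.4f, %d undefined\n",
                mean(off, na.rm = TRUE), suppressWarnings(max(off, na.rm = TRUE)),
                sum(is.na(off))))
  }
  invisible(x)
}
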