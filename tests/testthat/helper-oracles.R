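# Independent brute-force oracles for the STTC. Deliberately naive
# (explicit interval merging, exhaustive pairwise coincidence checks) so
# they share no code path with the package's vectorized implementation.

oracle_tiled_fraction <- function(times, dt, duration) {
  if (!length(times)) return(0)
  ivs <- lapply(times, function(t) c(max(t - dt, 0), min(t + dt, duration)))
  ivs <- ivs[order(vapply(ivs, `[`, numeric(1), 1))]
  total <- 0
  cur <- ivs[[1]]
  for (iv in ivs[-1]) {
    if (iv[1] <= cur[2]) {
      cur[2] <- max(cur[2], iv[2])
    } else {
      total <- total + (cur[2] - cur[1])
      cur <- iv
    }
  }
  total <- total + (cur[2] - cur[1])
  total / duration
}

oracle_coincident_fraction <- function(a, b, dt) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  hits <- 0L
  for (t in a) {
    if (any(abs(t - b) <= dt)) hits <- hits + 1L
  }
  hits / length(a)
}

oracle_sttc <- function(a, b, dt, duration) {
  if (!length(a) || !length(b)) return(NA_real_)
  ta <- oracle_tiled_fraction(a, dt, duration)
  tb <- oracle_tiled_fraction(b, dt, duration)
  pa <- oracle_coincident_fraction(a, b, dt)
  pb <- oracle_coincident_fraction(b, a, dt)
  if (1 - pa * tb == 0 || 1 - pb * ta == 0) return(NA_real_)
  0.5 * ((pa - tb) / (1 - pa * tb) + (pb - ta) / (1 - pb * ta))
}

# Random small train on [0, duration); n can be 0. Includes spikes near the
# window edges so tile clipping is exercised.
random_times <- function(n, duration) {
  if (n == 0L) return(numeric(0))
  sort(runif(n, 0, duration))
}

# Match detected spike times to ground truth within a tolerance; returns
# list(recall, n_extra). Greedy one-to-one matching on sorted times.
match_spikes <- function(detected, truth, tol_s) {
  used <- rep(FALSE, length(detected))
  hits <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = if (length(truth)) hits / length(truth) else NA_real_,
       n_extra = sum(!used))
}
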