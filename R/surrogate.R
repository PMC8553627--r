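#' Temporally randomize a spike matrix
#'
#' The default surrogate scheme: each electrode's spike times are redrawn
#' independently and uniformly on `[0, T)` and sorted, with the spike
#' count of every electrode preserved exactly -- so the across-electrode
#' firing-rate distribution of the surrogate is identical to the
#' original's while all temporal structure (and hence synchrony) is
#' destroyed. Alternative schemes preserving more structure are available
#' via `scheme`: `"isi_shuffle"` permutes each train's inter-spike
#' intervals (preserving the ISI distribution per train), `"jitter"`
#' displaces each spike by uniform noise of half-width `jitter_s` (wrapped
#' into the window).
#'
#' @param spikes A [spike_matrix()].
#' @param seed Integer seed; each train uses a derived substream.
#' @param scheme `"uniform"` (default), `"isi_shuffle"` or `"jitter"`.
#' @param jitter_s Half-width of the jitter window in seconds (for
#'   `scheme = "jitter"`).
#' @return A [spike_matrix()] with identical electrode IDs, duration and
#'   per-electrode spike counts.
#' @examples
#' sm <- spike_matrix(list(c(1, 2, 3), numeric(0)), 10)
#' randomize_spike_matrix(sm, seed = 1)
#' @export
randomize_spike_matrix <- function(spikes, seed,
                                   scheme = c("uniform", "isi_shuffle", "jitter"),
                                   jitter_s = 0.35) {
  stopifnot(inherits(spikes, "spike_matrix"))
  scheme <- match.arg(scheme)
  dur <- spikes$duration_s
  trains <- lapply(seq_along(spikes$trains), function(i) {
    tt <- spikes$trains[[i]]
    n <- length(tt)
    if (n == 0L) return(numeric(0))
    with_seed(substream_seed(seed, i), {
      new <- switch(scheme,
        uniform = sort(stats::runif(n, 0, dur)),
        isi_shuffle = {
          isi <- diff(c(0, tt))
          cumsum(sample(isi))
        },
        jitter = {
          j <- tt + stats::runif(n, -jitter_s, jitter_s)
          sort(j %% dur)
        }
      )
      new[new >= dur] <- new[new >= dur] - dur # guard for isi_shuffle tail
      new <- sort(new)
      # break (measure-zero) ties so trains stay strictly increasing
      while (any(diff(new) <= 0)) {
        k <- which(diff(new) <= 0) + 1L
        new[k] <- new[k] + 1e-9
        new <- sort(new %% dur)
      }
      new
    })
  })
  spike_matrix(trains, dur, electrode_ids = spikes$electrode_ids)
}

#' Build a surrogate null ensemble
#'
#' Repeats for `config$n_surrogates` surrogates: randomize the spike
#' matrix ([randomize_spike_matrix()]), compute the STTC matrix at the
#' configured synchronicity window, threshold it at `edge_threshold`, and
#' record the binary adjacency summary (degree distribution, mean degree,
#' edge count). The observed (unrandomized) graph's metrics are recorded
#' alongside as the reference. Per-surrogate seeds derive from the root
#' seed by fixed offsets, so the ensemble is reproducible and independent
#' of execution order.
#'
#' @param spikes The observed [spike_matrix()].
#' @param config An [mea_config()]; uses `sttc_dt_ms`, `edge_threshold`,
#'   `n_surrogates`, `seed`.
#' @param scheme Randomization scheme passed to
#'   [randomize_spike_matrix()].
#' @return An object of class `mea_null_ensemble`: `n_surrogates`, `seed`,
#'   `per_surrogate` (data frame `mean_degree,n_edges`), `degree_dists`
#'   (surrogates x degrees count matrix), `observed` (same metrics plus
#'   the observed graph), `comparison` (see [compare_to_null()]).
#' @examples
#' sm <- gen_correlated_trains(6, 2, 0.9, 60, seed = 1)$spikes
#' ens <- build_null_ensemble(sm, mea_config(n_surrogates = 5))
#' ens$comparison$exceedance_mean_degree
#' @export
build_null_ensemble <- function(spikes, config = mea_config(),
                                scheme = "uniform") {
  stopifnot(inherits(spikes, "spike_matrix"))
  config <- validate_config(config)
  dt_s <- config$sttc_dt_ms / 1000
  thr <- config$edge_threshold
  n_sur <- config$n_surrogates

  observed_graph <- build_graph(sttc_matrix(spikes, dt_s), spikes, thr)
  n <- length(spikes)
  counts <- lengths(spikes$trains)

  mean_deg <- numeric(n_sur)
  n_edges <- integer(n_sur)
  dists <- matrix(0L, nrow = n_sur, ncol = n,
                  dimnames = list(NULL, 0:(n - 1L)))
  for (s in seq_len(n_sur)) {
    surr <- randomize_spike_matrix(spikes, substream_seed(config$seed, 100000L + s),
                                   scheme = scheme)
    stopifnot(identical(lengths(surr$trains), counts)) # count conservation
    g <- build_graph(sttc_matrix(surr, dt_s), surr, thr)
    mean_deg[s] <- mean(g$nodes$degree)
    n_edges[s] <- nrow(g$edges)
    dists[s, ] <- degree_distribution(g)
  }
  ens <- structure(list(
    n_surrogates = n_sur, seed = config$seed, scheme = scheme,
    per_surrogate = data.frame(mean_degree = mean_deg, n_edges = n_edges),
    degree_dists = dists,
    observed = list(graph = observed_graph,
                    mean_degree = mean(observed_graph$nodes$degree),
                    n_edges = nrow(observed_graph$edges),
                    degree_dist = degree_distribution(observed_graph))
  ), class = "mea_null_ensemble")
  ens$comparison <- compare_to_null(observed_graph, ens)
  ens
}

#' Compare an observed graph against a surrogate ensemble
#'
#' Reports numbers only, no verdicts: (i) the empirical exceedance
#' fraction `(1 + #\{surrogates >= observed\}) / (n_surrogates + 1)` for
#' mean degree and edge count (the add-one convention avoids zero
#' p-values; small values mean the observed network is denser than
#' essentially all surrogates); (ii) the two-sample Kolmogorov-Smirnov
#' statistic between the observed node-degree values and the pooled
#' surrogate degrees.
#'
#' @param observed_graph The observed [build_graph()] result.
#' @param ensemble An [build_null_ensemble()] result.
#' @return List: `exceedance_mean_degree`, `exceedance_n_edges`,
#'   `ks_degree`.
#' @export
compare_to_null <- function(observed_graph, ensemble) {
  stopifnot(inherits(observed_graph, "mea_graph"),
            inherits(ensemble, "mea_null_ensemble"))
  n_sur <- ensemble$n_surrogates
  if (n_sur < 1L) stop_validation("ensemble is empty")
  obs_md <- mean(observed_graph$nodes$degree)
  obs_ne <- nrow(observed_graph$edges)
  exc_md <- (1 + sum(ensemble$per_surrogate$mean_degree >= obs_md)) / (n_sur + 1)
  exc_ne <- (1 + sum(ensemble$per_surrogate$n_edges >= obs_ne)) / (n_sur + 1)
  # pooled surrogate degree values, expanded from the count matrix
  degs <- as.integer(colnames(ensemble$degree_dists))
  pooled <- rep(degs, colSums(ensemble$degree_dists))
  list(
    exceedance_mean_degree = exc_md,
    exceedance_n_edges = exc_ne,
    ks_degree = ks_statistic(observed_graph$nodes$degree, pooled)
  )
}

# Exact two-sample KS statistic (ties allowed; ecdf-based).
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  grid <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

#' @export
print.mea_null_ensemble <- function(x, ...) {
  cat(sprintf("Surrogate null ensemble: %d surrogates (%s scheme)\n",
              x$n_surrogates, x$scheme))
  cat(sprintf("  observed mean degree %.3f vs surrogate %.3f (exceedance %.4f)\n",
              x$observed$mean_degree, mean(x$per_surrogate$mean_degree),
              x$comparison$exceedance_mean_degree))
  invisible(x)
}
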