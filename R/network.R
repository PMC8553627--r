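#' Build the thresholded functional-connectivity graph
#'
#' Places an edge between electrodes `i` and `j` (i != j) iff their STTC
#' is defined and *strictly* exceeds `edge_threshold` (so an entry exactly
#' at the threshold is excluded, and undefined `NA` entries never create
#' edges). The edge weight is the STTC value. Each node carries its binary
#' degree, firing rate and spike count; electrodes with empty trains are
#' retained with degree 0 and flagged, so the node count always equals the
#' array size.
#'
#' @param sttc An [sttc_matrix()].
#' @param spikes The [spike_matrix()] the STTC matrix was computed from
#'   (same electrodes, used for firing rates).
#' @param edge_threshold STTC value edges must strictly exceed
#'   (default 0.6).
#' @return An object of class `mea_graph`: list with `nodes` (data frame
#'   `electrode_id,degree,firing_rate_hz,n_spikes,defined`), `edges` (data
#'   frame `source,target,sttc`), `adjacency` (binary symmetric matrix,
#'   zero diagonal) and `threshold`.
#' @examples
#' sm <- spike_matrix(list(c(1, 1.1), c(1, 1.1), 8), 10)
#' g <- build_graph(sttc_matrix(sm, 0.175), sm)
#' g$nodes
#' @export
build_graph <- function(sttc, spikes, edge_threshold = 0.6) {
  stopifnot(inherits(sttc, "sttc_matrix"), inherits(spikes, "spike_matrix"))
  if (!identical(sttc$electrode_ids, spikes$electrode_ids)) {
    stop_validation("STTC matrix and spike matrix cover different electrodes")
  }
  if (!is_scalar_num(edge_threshold) || edge_threshold < 0 || edge_threshold > 1) {
    stop_validation("`edge_threshold` must lie in [0, 1]")
  }
  v <- sttc$values
  n <- nrow(v)
  adj <- !is.na(v) & v > edge_threshold
  diag(adj) <- FALSE
  adj <- adj * 1L
  deg <- rowSums(adj)
  counts <- lengths(spikes$trains)
  nodes <- data.frame(
    electrode_id = spikes$electrode_ids,
    degree = as.integer(deg),
    firing_rate_hz = counts / spikes$duration_s,
    n_spikes = as.integer(counts),
    defined = counts > 0L
  )
  ut <- which(upper.tri(v) & adj == 1L, arr.ind = TRUE)
  edges <- data.frame(
    source = spikes$electrode_ids[ut[, 1]],
    target = spikes$electrode_ids[ut[, 2]],
    sttc = v[ut]
  )
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, adjacency = adj,
                 threshold = edge_threshold),
            class = "mea_graph")
}

#' @export
print.mea_graph <- function(x, ...) {
  cat(sprintf("Functional connectivity graph: %d nodes, %d edges (STTC > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  cat(sprintf("  mean degree %.3f; mean firing rate %.4g Hz\n",
              mean(x$nodes$degree), mean(x$nodes$firing_rate_hz)))
  invisible(x)
}

#' Node degree distribution
#'
#' Counts of nodes at each binary degree `0 .. N-1`; the counts sum to the
#' number of electrodes.
#'
#' @param graph An [build_graph()] result.
#' @return Named integer vector of length `N` (names = degree values).
#' @examples
#' sm <- spike_matrix(list(c(1, 1.1), c(1, 1.1), 8), 10)
#' degree_distribution(build_graph(sttc_matrix(sm, 0.175), sm))
#' @export
degree_distribution <- function(graph) {
  stopifnot(inherits(graph, "mea_graph"))
  n <- nrow(graph$nodes)
  tab <- tabulate(graph$nodes$degree + 1L, nbins = n)
  names(tab) <- 0:(n - 1L)
  tab
}

#' Global summary metrics of a connectivity graph
#'
#' @param graph An [build_graph()] result.
#' @return List: `n_nodes`, `n_edges`, `mean_degree`, `edge_density`
#'   (edges / possible pairs), `mean_firing_rate_hz`, `total_spikes`.
#' @export
graph_metrics <- function(graph) {
  stopifnot(inherits(graph, "mea_graph"))
  n <- nrow(graph$nodes)
  e <- nrow(graph$edges)
  list(
    n_nodes = n,
    n_edges = e,
    mean_degree = mean(graph$nodes$degree),
    edge_density = if (n > 1) e / (n * (n - 1) / 2) else 0,
    mean_firing_rate_hz = mean(graph$nodes$firing_rate_hz),
    total_spikes = sum(graph$nodes$n_spikes)
  )
}

#' Convert a connectivity graph to igraph
#'
#' Optional bridge for external analysis or GraphML export
#' (`igraph::write_graph(g, path, format = "graphml")`).
#'
#' @param graph An [build_graph()] result.
#' @return An `igraph` object with node attributes `degree`,
#'   `firing_rate_hz`, `n_spikes` and edge attribute `weight` (the STTC).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "mea_graph"))
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for as_igraph()", call. = FALSE)
  }
  verts <- graph$nodes
  verts$name <- as.character(verts$electrode_id)
  edges <- graph$edges
  if (nrow(edges)) {
    edges <- data.frame(from = as.character(edges$source),
                        to = as.character(edges$target),
                        weight = edges$sttc)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}
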