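#' Build the thresholded functional-connectivity graph
#'
#' Electrodes become graph vertices and correlation coefficients edge
#' weights; edges weaker than the threshold (0.1) are removed, edges at
#' exactly the threshold are kept. Firing rates and node labels are attached
#' as vertex attributes.
#'
#' @param summary a `connectivity_summary` from [correlation_matrices].
#' @param firing_rates named numeric vector of per-electrode rates (Hz);
#'   optional.
#' @param electrode_map optional [electrode_map] for vertex node labels.
#' @param edge_threshold minimum retained edge weight.
#' @return An [igraph::igraph] weighted undirected graph.
#' @export
build_graph <- function(summary, firing_rates = NULL, electrode_map = NULL,
                        edge_threshold = 0.1) {
  A <- summary$electrode_matrix
  A[is.na(A)] <- 0
  A[A < edge_threshold] <- 0
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(firing_rates))
    igraph::V(g)$firing_rate <- unname(firing_rates[igraph::V(g)$name])
  if (!is.null(electrode_map)) {
    node_of <- setNames(electrode_map$node_label, electrode_map$electrode_id)
    igraph::V(g)$node_label <- unname(node_of[igraph::V(g)$name])
  }
  g
}

#' Louvain community detection with restarts
#'
#' Runs the Louvain algorithm `n_restarts` times under a seeded RNG and
#' keeps the partition with the highest weighted modularity
#' `Q = sum_i (e_ii - a_i^2)`. With a fixed seed the result is reproducible
#' bit for bit; ties are broken by the first partition found.
#'
#' @param g weighted undirected [igraph::igraph] with >= 1 edge.
#' @param gamma resolution parameter (1 = plain modularity).
#' @param n_restarts number of restarts.
#' @param seed RNG seed.
#' @return List with `membership` (named, contiguous integer community ids),
#'   `modularity` (best Q) and `n_communities`; for an edgeless graph, `NA`s
#'   with attribute `reason`.
#' @export
louvain_modularity <- function(g, gamma = 1, n_restarts = 100, seed = 1) {
  if (igraph::ecount(g) == 0)
    return(structure(list(membership = NULL, modularity = NA_real_,
                          n_communities = NA_integer_),
                     reason = "edgeless graph"))
  w <- igraph::E(g)$weight
  best_q <- -Inf; best_m <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, weights = w, resolution = gamma)
      q <- igraph::modularity(g, igraph::membership(cl), weights = w)
      if (q > best_q) { best_q <- q; best_m <- igraph::membership(cl) }
    }
  })
  m <- as.integer(factor(best_m, levels = unique(best_m)))
  names(m) <- igraph::V(g)$name
  list(membership = m, modularity = best_q,
       n_communities = length(unique(m)))
}

#' Weighted pagerank centrality
#'
#' @param g an [igraph::igraph]; edge weights are used when present.
#' @param damping damping factor.
#' @return Named numeric vector summing to 1.
#' @export
pagerank_centrality <- function(g, damping = 0.85) {
  if (igraph::vcount(g) == 0) stop("pagerank_centrality: empty graph")
  igraph::page_rank(g, damping = damping,
                    weights = if (igraph::ecount(g)) igraph::E(g)$weight
                    else NULL)$vector
}

#' Full graph summary of a connectivity matrix
#'
#' Convenience wrapper: builds the thresholded graph, runs Louvain with
#' restarts, and computes pagerank.
#'
#' @inheritParams build_graph
#' @param config an [analysis_config].
#' @param seed RNG seed for the Louvain restarts.
#' @return List of class `graph_summary` with `graph`, `membership`,
#'   `modularity`, `n_communities` and `pagerank`.
#' @export
graph_summary <- function(summary, firing_rates = NULL, electrode_map = NULL,
                          config = analysis_config(), seed = 1) {
  g <- build_graph(summary, firing_rates, electrode_map, config$edge_threshold)
  lv <- louvain_modularity(g, gamma = config$louvain_gamma,
                           n_restarts = config$louvain_restarts, seed = seed)
  structure(list(graph = g, membership = lv$membership,
                 modularity = lv$modularity,
                 n_communities = lv$n_communities,
                 pagerank = pagerank_centrality(g, config$pagerank_damping)),
            class = "graph_summary")
}
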