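# accept a phyllonet_men, an igraph, or an adjacency matrix; topology
# metrics use the unsigned, unweighted simple graph
as_unweighted_graph <- function(net) {
  g <- if (inherits(net, "phyllonet_men")) net$graph
  else if (igraph::is_igraph(net)) net
  else if (is.matrix(net)) igraph::graph_from_adjacency_matrix(net != 0, mode = "undirected")
  else abort("expected a phyllonet_men, igraph, or adjacency matrix")
  g <- igraph::simplify(g)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' Natural connectivity of a network
#'
#' The natural connectivity is the logarithm of the average eigenvalue
#' exponential of the (unsigned, unweighted) adjacency matrix,
#' `ln(mean(exp(lambda_i)))` -- a spectral measure of structural robustness
#' that quantifies the redundancy of closed walks.
#'
#' @param net A `phyllonet_men`, igraph, or adjacency matrix.
#' @return Numeric scalar; 0 for an edgeless graph.
#' @export
#' @examples
#' natural_connectivity(igraph::make_full_graph(3))  # ~0.9963
natural_connectivity <- function(net) {
  g <- as_unweighted_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) abort("network has no nodes")
  if (igraph::ecount(g) == 0) return(0)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
  lam <- eigen(a * 1, symmetric = TRUE, only.values = TRUE)$values
  # average exp(lambda) via log-sum-exp for numerical safety
  mx <- max(lam)
  mx + log(mean(exp(lam - mx)))
}

#' Global efficiency of a network
#'
#' Mean inverse shortest-path distance over all ordered node pairs, with
#' unreachable pairs contributing zero; unweighted paths.
#'
#' @inheritParams natural_connectivity
#' @return Numeric in \[0, 1\].
#' @export
global_efficiency <- function(net) {
  g <- as_unweighted_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("need at least 2 nodes")
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Average shortest path length
#'
#' Mean unweighted shortest-path distance over connected (reachable)
#' ordered pairs only; `NaN` with a warning if no pair is reachable.
#'
#' @inheritParams natural_connectivity
#' @return Numeric scalar.
#' @export
avg_path_length <- function(net) {
  g <- as_unweighted_graph(net)
  d <- igraph::distances(g, weights = NA)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0) {
    warn("no reachable pairs: average path length undefined")
    return(NaN)
  }
  mean(d)
}

#' Complexity indices of a network
#'
#' Freeman degree centralization, the global (average local) clustering
#' coefficient, and the Newman modularity Q of a supplied partition, along
#' with basic size and sign counts -- the complexity panel compared against
#' random-graph ensembles.
#'
#' @param net A `phyllonet_men` object (sign information is read from its
#'   edges when present) or igraph.
#' @param partition A [detect_modules()] partition on the same graph; when
#'   `NULL` it is computed with the fast-greedy algorithm.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `pos_frac`, `avg_l`,
#'   `global_efficiency`, `natural_connectivity`, `degree_centralization`,
#'   `clustering_coefficient`, `modularity`.
#' @export
complexity_indices <- function(net, partition = NULL) {
  g <- as_unweighted_graph(net)
  n <- igraph::vcount(g)
  if (is.null(partition)) partition <- detect_modules(net)
  memb <- partition$membership$module[match(igraph::V(g)$name,
                                            partition$membership$node)]
  if (n < 3) {
    warn("degree centralization undefined for fewer than 3 nodes; returning 0")
    centr <- 0
  } else {
    k <- igraph::degree(g)
    centr <- sum(max(k) - k) / ((n - 1) * (n - 2))
  }
  pos_frac <- if (inherits(net, "phyllonet_men") && nrow(net$edges)) {
    mean(net$edges$sign == "+")
  } else NA_real_
  tibble(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    pos_frac = pos_frac,
    avg_l = avg_path_length(g),
    global_efficiency = global_efficiency(g),
    natural_connectivity = natural_connectivity(g),
    degree_centralization = centr,
    clustering_coefficient = igraph::transitivity(g, type = "localaverage",
                                                  isolates = "zero"),
    modularity = igraph::modularity(g, memb)
  )
}
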