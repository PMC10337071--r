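#' Build a signed co-occurrence network at a correlation threshold
#'
#' Keeps an edge between two ASVs iff its BH q-value is at most `fdr` and
#' `|rho|` is at least `threshold`; the correlation sign is stored as an
#' edge attribute.  Isolated nodes are dropped from the graph.
#'
#' @param corr A [spearman_matrix()] object.
#' @param threshold Correlation cutoff in (0, 1), typically from
#'   [select_transition()].
#' @param fdr Significance mask (default 0.05).
#' @return An object of class `phyllonet_men`: list with `graph` (igraph),
#'   `edges` (tibble `from`, `to`, `rho`, `sign`), `threshold`, `n_samples`.
#'   An empty edge set yields a warning and an empty network object.
#' @export
build_network <- function(corr, threshold, fdr = 0.05) {
  stopifnot(inherits(corr, "phyllonet_cor"))
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  up <- which(upper.tri(corr$rho), arr.ind = TRUE)
  keep <- corr$qval[up] <= fdr & abs(corr$rho[up]) >= threshold
  edges <- tibble(
    from = corr$asv_ids[up[keep, 1]],
    to = corr$asv_ids[up[keep, 2]],
    rho = corr$rho[up][keep],
    sign = ifelse(corr$rho[up][keep] >= 0, "+", "-")
  )
  if (nrow(edges) == 0) warn("empty network: no correlation passes the threshold")
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE)
  igraph::E(g)$rho <- edges$rho
  igraph::E(g)$sign <- edges$sign
  structure(
    list(graph = g, edges = edges, threshold = threshold, n_samples = corr$n),
    class = "phyllonet_men"
  )
}

#' @export
print.phyllonet_men <- function(x, ...) {
  cat("Co-occurrence network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (threshold",
      format(x$threshold, digits = 3), ")\n")
  invisible(x)
}

#' @describeIn build_network Edge table of the network.
#' @param x A `phyllonet_men` object.
#' @param ... Unused.
#' @export
tidy.phyllonet_men <- function(x, ...) x$edges

#' @describeIn build_network One-row summary: node/edge counts, positive
#'   edge fraction, threshold.
#' @export
glance.phyllonet_men <- function(x, ...) {
  tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    pos_frac = if (nrow(x$edges)) mean(x$edges$sign == "+") else NA_real_,
    threshold = x$threshold
  )
}

#' Network nodes
#' @param net A `phyllonet_men` object.
#' @return Character vector of ASV ids in the graph.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Write a network as a weighted edge list and GraphML
#'
#' @param net A `phyllonet_men` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- dplyr::rename(net$edges, source = "from", target = "to")
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(net$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  invisible(dir)
}
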