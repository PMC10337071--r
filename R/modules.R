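#' Detect network modules with the fast-greedy algorithm
#'
#' Greedy modularity maximisation (Clauset-Newman-Moore) on the unweighted
#' simple graph; deterministic for a given graph.
#'
#' @param net A `phyllonet_men` or igraph.
#' @return An object of class `phyllonet_partition`: list with `membership`
#'   (tibble `node`, `module`), `sizes` (tibble `module`, `n`), and
#'   `modularity` (the Q of the partition).
#' @export
detect_modules <- function(net) {
  g <- as_unweighted_graph(net)
  if (igraph::vcount(g) == 0) abort("network is empty")
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  memb <- igraph::membership(cl)
  membership <- tibble(node = igraph::V(g)$name, module = as.integer(memb))
  structure(
    list(
      membership = membership,
      sizes = dplyr::count(membership, .data$module, name = "n"),
      modularity = igraph::modularity(g, memb)
    ),
    class = "phyllonet_partition"
  )
}

#' @export
print.phyllonet_partition <- function(x, ...) {
  cat("Module partition:", nrow(x$sizes), "modules, Q =",
      format(x$modularity, digits = 3), "\n")
  invisible(x)
}

#' @describeIn detect_modules Node-to-module assignment table.
#' @param x A `phyllonet_partition` object.
#' @param ... Unused.
#' @export
tidy.phyllonet_partition <- function(x, ...) x$membership

#' Module eigengene: PC1 of a module's member abundances
#'
#' The eigengene summarises the per-sample variation of a module: the first
#' principal component of the standardised (column z-scored) relative
#' abundances of its members, sign-oriented so that it correlates
#' non-negatively with the members' mean standardised abundance.
#'
#' @param abund Abundance tibble.
#' @param members Character vector of member ASV ids (at least 5, the
#'   conventional minimum for a stable eigengene).
#' @return A list: `scores` (per-sample eigengene, named by sample),
#'   `var_explained` (fraction of member variance on PC1).
#' @export
module_eigengene <- function(abund, members) {
  if (length(members) < 5) abort("eigengenes are computed for modules with 5 or more nodes")
  m <- abund_matrix(abund)
  missing <- setdiff(members, colnames(m))
  if (length(missing)) abort(paste("members absent from abundance table:",
                                   paste(missing, collapse = ", ")))
  rel <- m[, members, drop = FALSE] / rowSums(m)
  keep <- apply(rel, 2, sd) > 0
  if (!all(keep)) {
    warn(paste(sum(!keep), "constant member column(s) dropped"))
    rel <- rel[, keep, drop = FALSE]
  }
  z <- scale(rel)
  sv <- svd(z)
  scores <- sv$u[, 1] * sv$d[1]
  if (cor(scores, rowMeans(z)) < 0) scores <- -scores
  list(
    scores = setNames(as.numeric(scores), rownames(m)),
    var_explained = sv$d[1]^2 / sum(sv$d^2)
  )
}

#' Eigengenes for all sufficiently large modules
#'
#' @param partition A [detect_modules()] partition.
#' @param abund Abundance tibble covering the partition's nodes.
#' @param min_size Minimum module size for an eigengene (default 5).
#' @return A list: `scores` (tibble `sample_id` + one column per module,
#'   named `M<id>`), `var_explained` (named numeric).
#' @export
module_eigengenes <- function(partition, abund, min_size = 5) {
  big <- partition$sizes$module[partition$sizes$n >= min_size]
  if (length(big) == 0) abort("no module reaches the minimum size")
  egs <- purrr::map(big, function(mod) {
    members <- partition$membership$node[partition$membership$module == mod]
    module_eigengene(abund, members)
  })
  scores <- dplyr::bind_cols(
    tibble(sample_id = abund$sample_id),
    as_tibble(setNames(purrr::map(egs, "scores"), paste0("M", big)))
  )
  list(scores = scores,
       var_explained = setNames(purrr::map_dbl(egs, "var_explained"),
                                paste0("M", big)))
}
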