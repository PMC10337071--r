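#' Order-level enrichment of positive regulation taxa
#'
#' For each fungal order represented in the network, tests whether the
#' positive regulation taxa (PRT) overrepresent that order with a one-sided
#' hypergeometric upper-tail test `P(X >= k)` (population = all network
#' ASVs with a known order, successes = order members, draws = PRT),
#' equivalent to a one-sided Fisher's exact test; BH FDR across orders.
#' Orders with fewer than `min_order_size` network members are skipped.
#'
#' @param prt Character vector of PRT node ids.
#' @param mens_nodes Character vector of all network node ids.
#' @param taxonomy Taxonomy tibble (`asv_id`, ..., `order`, ...).
#' @param fdr Enrichment threshold (default 0.05).
#' @param min_order_size Minimum network members per tested order
#'   (default 2).
#' @return Tibble: `order`, `n_prt_in_order`, `n_order_in_mens`,
#'   `n_prt_total`, `n_mens_total`, `p`, `fdr`, `enriched`, plus attributes
#'   `n_unknown_order` and `skipped_orders`.
#' @export
order_enrichment <- function(prt, mens_nodes, taxonomy, fdr = 0.05,
                             min_order_size = 2) {
  ord <- taxonomy$order[match(mens_nodes, taxonomy$asv_id)]
  unknown <- is.na(ord)
  nodes <- mens_nodes[!unknown]
  ord <- ord[!unknown]
  n_total <- length(nodes)
  prt <- intersect(prt, nodes)
  n_prt <- length(prt)

  counts <- dplyr::count(tibble(order = ord), .data$order, name = "n_order_in_mens")
  skipped <- counts$order[counts$n_order_in_mens < min_order_size]
  counts <- counts[counts$n_order_in_mens >= min_order_size, , drop = FALSE]
  res <- dplyr::bind_rows(purrr::map(seq_len(nrow(counts)), function(i) {
    o <- counts$order[i]
    n_ord <- counts$n_order_in_mens[i]
    k <- sum(ord[match(prt, nodes)] == o)
    p <- if (n_prt == 0) 1 else
      phyper(k - 1, n_ord, n_total - n_ord, n_prt, lower.tail = FALSE)
    tibble(order = o, n_prt_in_order = k, n_order_in_mens = n_ord,
           n_prt_total = n_prt, n_mens_total = n_total, p = p)
  }))
  if (nrow(res)) {
    res$fdr <- bh_adjust(res$p)
    res$enriched <- res$fdr < fdr
    res <- dplyr::arrange(res, .data$p)
  }
  attr(res, "n_unknown_order") <- sum(unknown)
  attr(res, "skipped_orders") <- skipped
  res
}

#' Build a rank-layered tree from a taxonomy table
#'
#' Nests ASV tips under genus, family, order, class, phylum and kingdom
#' nodes and returns the tree as an `ape` phylo object (round-trippable
#' newick).  Conflicting lineages (the same genus under two families, and
#' likewise up the ranks) raise an error naming the conflict.
#'
#' @param taxonomy Taxonomy tibble (`asv_id`, `kingdom`..`genus`).
#' @return An `ape::phylo` tree whose tips are the ASV ids.
#' @export
taxonomy_tree <- function(taxonomy) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if (!all(c("asv_id", ranks) %in% names(taxonomy))) {
    abort("taxonomy must contain asv_id and kingdom..genus columns")
  }
  for (i in seq_along(ranks)[-1]) {
    child <- ranks[i]; parent <- ranks[i - 1]
    map <- unique(taxonomy[c(child, parent)])
    dup <- map[[child]][duplicated(map[[child]])]
    if (length(dup)) {
      abort(paste0("rank conflict: ", child, " '", dup[1],
                   "' appears under multiple ", parent, " values"))
    }
  }
  build <- function(tbl, level) {
    if (level > length(ranks)) {
      return(paste(tbl$asv_id, collapse = ","))
    }
    groups <- split(tbl, tbl[[ranks[level]]])
    paste(purrr::imap_chr(groups, function(sub, nm) {
      inner <- build(sub, level + 1)
      paste0("(", inner, ")", gsub("[ ();,:]", "_", nm))
    }), collapse = ",")
  }
  nwk <- paste0("(", build(taxonomy, 1), ");")
  ape::read.tree(text = nwk)
}

#' Presence of positive regulation genera across plant species
#'
#' Maps each species' PRT set to genera and reports a genus x species
#' presence matrix; genera present in every species are flagged conserved.
#'
#' @param prt_by_species Named list: species -> character vector of PRT
#'   node ids.
#' @param taxonomy Taxonomy tibble covering the nodes.
#' @return Tibble: `genus`, one logical column per species, `conserved`.
#' @export
prt_presence <- function(prt_by_species, taxonomy) {
  if (length(prt_by_species) == 0) abort("need at least one species")
  genera_of <- function(nodes) {
    unique(na.omit(taxonomy$genus[match(nodes, taxonomy$asv_id)]))
  }
  per_species <- purrr::map(prt_by_species, genera_of)
  genera <- sort(unique(unlist(per_species)))
  out <- tibble(genus = genera)
  for (sp in names(per_species)) out[[sp]] <- genera %in% per_species[[sp]]
  out$conserved <- rowSums(as.matrix(out[names(per_species)])) ==
    length(per_species)
  out
}
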