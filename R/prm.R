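#' Identify positive regulation modules of total saponin content
#'
#' For every member of each candidate module, tests the Spearman
#' correlation of its abundance with total saponin content (BH FDR over all
#' tested members).  A module is a positive regulation module (PRM) when at
#' least half of its members are significantly positively correlated
#' (boundary inclusive).
#'
#' @param partition A [detect_modules()] partition.
#' @param abund Abundance tibble covering the partition's nodes.
#' @param total_saponin Per-sample total saponin content (named by sample
#'   or aligned with `abund` rows).
#' @param candidate_modules Module ids to test (typically the screened
#'   candidates); defaults to all modules with at least `min_size` nodes.
#' @param fdr Member-level significance threshold (default 0.05).
#' @param min_size Default candidate filter (default 5).
#' @return An object of class `phyllonet_prm`: list with `modules` (tibble
#'   `module`, `n_members`, `n_sig_positive`, `is_prm`) and `members`
#'   (tibble `node`, `module`, `rho`, `pval`, `fdr`, `sig_positive`).
#' @export
identify_prm <- function(partition, abund, total_saponin,
                         candidate_modules = NULL, fdr = 0.05, min_size = 5) {
  if (is.null(candidate_modules)) {
    candidate_modules <- partition$sizes$module[partition$sizes$n >= min_size]
  }
  memb <- dplyr::filter(partition$membership, .data$module %in% candidate_modules)
  if (nrow(memb) == 0) abort("no members in the candidate modules")
  m <- abund_matrix(abund)
  tot <- if (!is.null(names(total_saponin))) {
    total_saponin[rownames(m)]
  } else total_saponin
  stats_tbl <- dplyr::bind_rows(purrr::map(seq_len(nrow(memb)), function(i) {
    ct <- suppressWarnings(
      stats::cor.test(m[, memb$node[i]], tot, method = "spearman",
                      exact = FALSE))
    tibble(node = memb$node[i], module = memb$module[i],
           rho = unname(ct$estimate), pval = ct$p.value)
  }))
  stats_tbl$fdr <- bh_adjust(stats_tbl$pval)
  stats_tbl$sig_positive <- stats_tbl$fdr < fdr & stats_tbl$rho > 0
  mods <- dplyr::summarise(
    dplyr::group_by(stats_tbl, .data$module),
    n_members = dplyr::n(),
    n_sig_positive = sum(.data$sig_positive),
    .groups = "drop"
  )
  mods$is_prm <- mods$n_sig_positive >= mods$n_members / 2
  structure(list(modules = mods, members = stats_tbl),
            class = "phyllonet_prm")
}

#' @export
print.phyllonet_prm <- function(x, ...) {
  cat("PRM screen:", sum(x$modules$is_prm), "of", nrow(x$modules),
      "candidate modules are positive regulation modules\n")
  invisible(x)
}

#' @describeIn identify_prm Module-level PRM table.
#' @param x A `phyllonet_prm` object.
#' @param ... Unused.
#' @export
tidy.phyllonet_prm <- function(x, ...) x$modules

#' Compare node degree between PRM members and other network nodes
#'
#' Two-sided Wilcoxon rank-sum test on degrees (mid-rank ties; exact for
#' small tie-free samples, otherwise the normal approximation with
#' continuity correction).
#'
#' @param prm_nodes,other_nodes Character vectors of node ids; both must be
#'   non-empty.
#' @param net A `phyllonet_men` or igraph.
#' @return One-row tibble: `w`, `p`, `median_prm`, `median_other`.
#' @export
degree_compare <- function(prm_nodes, other_nodes, net) {
  if (length(prm_nodes) == 0 || length(other_nodes) == 0) {
    abort("both node groups must be non-empty")
  }
  g <- as_unweighted_graph(net)
  deg <- igraph::degree(g)
  x <- deg[prm_nodes]
  y <- deg[other_nodes]
  wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  p <- wt$p.value
  # fully tied samples give a degenerate normal approximation; no evidence
  # of a shift
  if (is.na(p) && length(unique(c(x, y))) == 1) p <- 1
  tibble(w = unname(wt$statistic), p = p,
         median_prm = median(x), median_other = median(y))
}

#' Functional guild composition of a node set
#'
#' Tallies guild fractions over a node set, keeping only probable and
#' highly probable guild predictions (lower-confidence calls and nodes
#' missing from the guild table fall into `unassigned`), and reports the
#' plant-associated aggregate (plant pathogen + endophyte + epiphyte).
#'
#' @param nodes Character vector of node ids.
#' @param guilds Guild tibble (`asv_id`, `guild`, `confidence`).
#' @return A list: `fractions` (tibble `guild`, `n`, `fraction`, summing to
#'   1 including `unassigned`), `plant_associated` (numeric fraction).
#' @export
guild_composition <- function(nodes, guilds) {
  g <- guilds$guild[match(nodes, guilds$asv_id)]
  conf <- guilds$confidence[match(nodes, guilds$asv_id)]
  ok <- !is.na(g) & !is.na(conf) & conf %in% c("Probable", "Highly Probable")
  g[!ok] <- "unassigned"
  fr <- dplyr::count(tibble(guild = g), .data$guild, name = "n")
  fr$fraction <- fr$n / sum(fr$n)
  plant <- sum(fr$fraction[fr$guild %in% c("plant_pathogen", "endophyte",
                                           "epiphyte", "plant pathogen")])
  list(fractions = fr, plant_associated = plant)
}

#' Extract positive regulation taxa from validated modules
#'
#' Positive regulation taxa (PRT) are the members of validated positive
#' regulation modules whose correlation with total saponin content is
#' significantly positive (FDR < `fdr`, rho > 0).
#'
#' @param prm A [identify_prm()] result.
#' @param modules Module ids validated by the path model (or retained via a
#'   documented collinearity exception); defaults to all flagged PRMs.
#' @param fdr Significance threshold (default 0.05).
#' @return Character vector of PRT node ids.
#' @export
identify_prt <- function(prm, modules = NULL, fdr = 0.05) {
  stopifnot(inherits(prm, "phyllonet_prm"))
  if (is.null(modules)) modules <- prm$modules$module[prm$modules$is_prm]
  mem <- dplyr::filter(prm$members, .data$module %in% modules,
                       .data$fdr < !!fdr, .data$rho > 0)
  mem$node
}
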