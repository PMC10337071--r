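# Spearman rho and BH q of every node profile against every environmental
# factor; the q family is all node x factor tests
node_env_correlations <- function(abund, env, fdr = 0.05) {
  m <- abund_matrix(abund)
  e <- meta_matrix(env)
  keep <- apply(e, 2, function(x) sd(x) > 0)
  if (!all(keep)) {
    warn(paste("constant environmental factor(s) skipped:",
               paste(colnames(e)[!keep], collapse = ", ")))
    e <- e[, keep, drop = FALSE]
  }
  n <- nrow(m)
  rho <- suppressWarnings(cor(m, e, method = "spearman"))
  rho[is.na(rho)] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1] <- 0
  qval <- matrix(bh_adjust(as.numeric(pval)), nrow(pval), ncol(pval),
                 dimnames = dimnames(pval))
  list(rho = rho, qval = qval, sig = qval <= fdr)
}

#' Test whether a link is environmentally driven
#'
#' A link is attributed to environmental filtering when some environmental
#' factor correlates significantly (Spearman, BH q <= `fdr` within the
#' node x factor family) with both endpoints and the endpoints' partial
#' Spearman correlation controlling that factor falls below the network
#' threshold -- i.e. the co-occurrence is explained away by shared
#' environmental response.
#'
#' @param asv_i,asv_j Endpoint ASV ids.
#' @param abund Abundance tibble containing both endpoints.
#' @param env Environment tibble (`sample_id` + numeric factors).
#' @param threshold The network's correlation threshold.
#' @param fdr Significance level for endpoint-factor correlations.
#' @return Logical scalar.
#' @export
env_link_test <- function(asv_i, asv_j, abund, env, threshold, fdr = 0.05) {
  ne <- node_env_correlations(abund[c("sample_id", asv_i, asv_j)], env, fdr)
  m <- abund_matrix(abund)
  e <- meta_matrix(env)
  for (f in colnames(ne$sig)) {
    if (ne$sig[asv_i, f] && ne$sig[asv_j, f]) {
      pc <- partial_spearman(m[, asv_i], m[, asv_j], e[, f])
      if (abs(pc) < threshold) return(TRUE)
    }
  }
  FALSE
}

#' Mantel correlation of one node's profile with spatial distance
#'
#' Bray-Curtis dissimilarity between samples for a single taxon reduces to
#' `|x_a - x_b| / (x_a + x_b)` (0 for double zeros); the Mantel statistic is
#' the Pearson correlation between that matrix and the Euclidean spatial
#' distance matrix, with a permutation p-value.
#'
#' @param profile Per-sample abundance vector.
#' @param coords Coordinates tibble (`sample_id`, `x`, `y`) aligned with
#'   `profile`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list `r`, `p` (`NA` with a warning for an all-zero profile).
#' @export
node_mantel <- function(profile, coords, n_perm = 999, seed = 1L) {
  if (length(profile) < 5) abort("need at least 5 samples for a Mantel test")
  if (all(profile == 0)) {
    warn("all-zero profile: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  s <- outer(profile, profile, "+")
  d_bc <- abs(outer(profile, profile, "-")) / ifelse(s == 0, 1, s)
  d_geo <- as.matrix(dist(cbind(coords$x, coords$y)))
  res <- withr::with_seed(seed, {
    vegan::mantel(stats::as.dist(d_bc), stats::as.dist(d_geo),
                  permutations = n_perm)
  })
  list(r = unname(res$statistic), p = res$signif)
}

#' Attribute network links to environment, dispersal, or biotic interaction
#'
#' Classifies every edge: `environment` if it passes [env_link_test()] for
#' any factor, `dispersal` if both endpoints are strongly dispersal-limited
#' (Mantel r >= `mantel_r_cut`, p < 0.05 against spatial distance),
#' `env&disp` if both, `biotic` otherwise.
#'
#' @param net A `phyllonet_men` object.
#' @param abund,env,coords Sample-aligned abundance, environment and
#'   coordinate tibbles.
#' @param mantel_r_cut Mantel r cutoff for dispersal limitation (default
#'   0.6).
#' @param fdr Significance level for the environmental test.
#' @param n_perm Mantel permutations (default 999).
#' @param seed Integer seed (per-node Mantel permutation streams are derived
#'   from it).
#' @return An object of class `phyllonet_lted`: list with `edges` (tibble
#'   `from`, `to`, `label`), `proportions` (tibble `label`, `n`,
#'   `proportion`), and `node_mantel` (tibble `node`, `r`, `p`,
#'   `dispersal_limited`).
#' @export
attribute_links <- function(net, abund, env, coords, mantel_r_cut = 0.6,
                            fdr = 0.05, n_perm = 999, seed = 1L) {
  stopifnot(inherits(net, "phyllonet_men"))
  check_sample_alignment(abund, env, coords)
  edges <- net$edges
  nodes <- network_nodes(net)
  m <- abund_matrix(abund)
  e <- meta_matrix(env)
  ne <- node_env_correlations(abund[c("sample_id", nodes)], env, fdr)

  env_driven <- vapply(seq_len(nrow(edges)), function(i) {
    a <- edges$from[i]; b <- edges$to[i]
    for (f in colnames(ne$sig)) {
      if (ne$sig[a, f] && ne$sig[b, f] &&
          abs(partial_spearman(m[, a], m[, b], e[, f])) < net$threshold) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))

  mant <- purrr::map(nodes, function(nd) {
    node_mantel(m[, nd], coords, n_perm = n_perm,
                seed = derive_seed(seed, paste0("mantel_", nd)))
  })
  node_mantel_tbl <- tibble(
    node = nodes,
    r = purrr::map_dbl(mant, "r"),
    p = purrr::map_dbl(mant, "p")
  )
  node_mantel_tbl$dispersal_limited <-
    !is.na(node_mantel_tbl$r) & node_mantel_tbl$r >= mantel_r_cut &
    node_mantel_tbl$p < 0.05
  dl <- setNames(node_mantel_tbl$dispersal_limited, node_mantel_tbl$node)
  disp_driven <- dl[edges$from] & dl[edges$to]

  label <- dplyr::case_when(
    env_driven & disp_driven ~ "env&disp",
    env_driven ~ "environment",
    disp_driven ~ "dispersal",
    TRUE ~ "biotic"
  )
  edges$label <- label
  props <- dplyr::count(edges, .data$label, name = "n")
  props$proportion <- props$n / sum(props$n)
  structure(
    list(edges = edges[c("from", "to", "label")], proportions = props,
         node_mantel = node_mantel_tbl),
    class = "phyllonet_lted"
  )
}

#' @export
print.phyllonet_lted <- function(x, ...) {
  cat("Link attribution over", sum(x$proportions$n), "edges:\n")
  print(x$proportions)
  invisible(x)
}

#' @describeIn attribute_links Per-edge attribution table.
#' @param x A `phyllonet_lted` object.
#' @param ... Unused.
#' @export
tidy.phyllonet_lted <- function(x, ...) x$edges
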