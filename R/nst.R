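#' Normalised stochasticity ratio of a subcommunity
#'
#' Quantifies how far observed between-sample dissimilarity sits from its
#' null expectation under random assembly.  The null model preserves each
#' sample's richness and draws taxa with probability proportional to their
#' occupancy (occurrence frequency across samples), permuting the sample's
#' observed non-zero abundances onto the drawn taxa; dissimilarity is
#' Ruzicka (quantitative Jaccard).  Each sample pair contributes
#' `min(D_obs, E_null) / max(D_obs, E_null)`; the ratio is 1 when observed
#' dissimilarity matches the null (fully stochastic assembly) and falls
#' towards 0 as selection pushes communities to be more similar (or more
#' divergent) than chance.  The mean over pairs, clamped to \[0, 1\], is
#' returned; lower values indicate more deterministic assembly.
#'
#' @param abund Subcommunity abundance tibble (`sample_id` + taxa), at
#'   least 4 samples and 2 taxa.
#' @param n_rand Number of null randomisations (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble of class `phyllonet_nst`: `nst`, `n_rand`,
#'   `null_model`, `seed`.
#' @export
nst <- function(abund, n_rand = 1000, seed = 1L) {
  m <- abund_matrix(abund)
  if (nrow(m) < 4) abort("need at least 4 samples for the stochasticity ratio")
  if (ncol(m) < 2) abort("need at least 2 taxa")
  d_obs <- as.matrix(vegan::vegdist(m, method = "jaccard"))
  n <- nrow(m)
  p <- ncol(m)
  occ <- colSums(m > 0)
  if (all(occ == 0)) abort("subcommunity is empty")
  richness <- rowSums(m > 0)

  e_sum <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (r in seq_len(n_rand)) {
      null_m <- matrix(0, n, p)
      for (s in seq_len(n)) {
        if (richness[s] == 0) next
        taxa <- sample.int(p, richness[s], prob = occ + 1e-12)
        vals <- m[s, m[s, ] > 0]
        null_m[s, taxa] <- sample(vals)
      }
      e_sum <- e_sum + as.matrix(vegan::vegdist(null_m, method = "jaccard"))
    }
  })
  e_null <- e_sum / n_rand
  up <- upper.tri(d_obs)
  d <- d_obs[up]
  e <- e_null[up]
  ratio <- ifelse(pmax(d, e) == 0, 1, pmin(d, e) / pmax(d, e))
  out <- tibble(nst = min(max(mean(ratio), 0), 1),
                n_rand = as.integer(n_rand),
                null_model = "occupancy-proportional, fixed richness, Ruzicka",
                seed = as.integer(seed))
  class(out) <- c("phyllonet_nst", class(out))
  out
}

#' Contrast assembly stochasticity between node groups
#'
#' Convenience wrapper computing the stochasticity ratio separately for a
#' focal node set (e.g. PRM members) and the remaining nodes of the same
#' network.
#'
#' @param abund Abundance tibble.
#' @param focal_nodes,other_nodes Character vectors of taxon ids.
#' @param n_rand,seed Passed to [nst()].
#' @return Tibble with a `group` column (`"focal"`, `"other"`).
#' @export
nst_contrast <- function(abund, focal_nodes, other_nodes,
                         n_rand = 1000, seed = 1L) {
  sub <- function(nodes) abund[c("sample_id", intersect(names(abund), nodes))]
  dplyr::bind_rows(
    dplyr::mutate(nst(sub(focal_nodes), n_rand, derive_seed(seed, "nst_focal")),
                  group = "focal", .before = 1),
    dplyr::mutate(nst(sub(other_nodes), n_rand, derive_seed(seed, "nst_other")),
                  group = "other", .before = 1)
  )
}
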