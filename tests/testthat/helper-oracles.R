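# Independent brute-force oracles, deliberately implemented differently
# from the package internals they check.

# natural connectivity via the matrix exponential trace (scaling-and-
# squaring Taylor series; no eigendecomposition)
bf_expm <- function(a) {
  nrm <- max(rowSums(abs(a)))
  k <- max(0, ceiling(log2(max(nrm, 1e-12))) + 4)
  a <- a / 2^k
  term <- diag(nrow(a))
  acc <- term
  for (i in 1:30) {
    term <- term %*% a / i
    acc <- acc + term
  }
  for (i in seq_len(k)) acc <- acc %*% acc
  acc
}

bf_natural_connectivity <- function(adj) {
  n <- nrow(adj)
  log(sum(diag(bf_expm(adj * 1))) / n)
}

# hand-rolled BFS distances (no igraph)
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] != 0))))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_avg_path_length <- function(adj) {
  d <- bf_distances(adj)
  d <- d[upper.tri(d)]
  mean(d[is.finite(d) & d > 0])
}

# Newman modularity Q = sum_i (e_ii - a_i^2) over module fractions
bf_modularity <- function(adj, membership) {
  m2 <- sum(adj)                      # 2m for a symmetric 0/1 matrix
  mods <- unique(membership)
  q <- 0
  for (s in mods) {
    in_s <- membership == s
    e_ss <- sum(adj[in_s, in_s]) / m2
    a_s <- sum(adj[in_s, ]) / m2
    q <- q + e_ss - a_s^2
  }
  q
}

# Spearman rho as Pearson on mid-ranks
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# BH step-up by the textbook formula
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# hypergeometric upper tail P(X >= k) by direct enumeration
bf_hyper_tail <- function(k, n_success, n_total, n_draw) {
  kk <- k:min(n_success, n_draw)
  sum(choose(n_success, kk) * choose(n_total - n_success, n_draw - kk)) /
    choose(n_total, n_draw)
}

# adjusted Rand index from the contingency table
bf_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# all set partitions of 1..n (for exhaustive modularity search, small n)
bf_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- bf_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
}

random_graph <- function(n, p, seed) {
  withr::with_seed(seed, igraph::sample_gnp(n, p))
}

# small deterministic abundance fixture
toy_abundance <- function(n = 12, seed = 7) {
  withr::with_seed(seed, {
    lam <- c(5, 10, 20, 40, 80, 160)
    m <- sapply(lam, function(l) rpois(n, l))
    dimnames(m) <- list(sprintf("S%02d", 1:n), paste0("ASV_", seq_along(lam)))
    phyllonet:::matrix_abund(m)
  })
}

# build a phyllonet_cor object directly from a rho matrix with all q = 0
cor_fixture <- function(rho, asv_ids = NULL, n = 30) {
  p <- nrow(rho)
  if (is.null(asv_ids)) asv_ids <- paste0("ASV_", seq_len(p))
  dimnames(rho) <- list(asv_ids, asv_ids)
  z <- matrix(0, p, p, dimnames = dimnames(rho))
  structure(list(rho = rho, pval = z, qval = z, n = n, asv_ids = asv_ids),
            class = "phyllonet_cor")
}

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- phyllonet::sim_config(seed = 1)
      sim <- phyllonet::simulate_community(cfg)
      ab <- phyllonet::abundance_filter(sim$abundance)
      corr <- phyllonet::spearman_matrix(ab)
      thr <- phyllonet::select_transition(
        phyllonet::rmt_scan(corr, 0.3, 0.95, 0.02))
      net <- phyllonet::build_network(corr, thr)
      cache <<- list(cfg = cfg, sim = sim, abund = ab, corr = corr,
                     threshold = thr, net = net,
                     partition = phyllonet::detect_modules(net))
    }
    cache
  }
})
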