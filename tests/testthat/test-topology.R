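test_that("natural connectivity matches hand-derived spectra and the expm oracle", {
  # K3: eigenvalues {2, -1, -1} -> ln((e^2 + 2e^-1)/3)
  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(k3), 0.9963, tolerance = 1e-4)
  # single edge: eigenvalues {1, -1} -> ln(cosh 1)
  e2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_equal(natural_connectivity(e2), log(cosh(1)), tolerance = 1e-12)
  expect_equal(natural_connectivity(e2), 0.4338, tolerance = 1e-4)
  # edgeless
  expect_equal(natural_connectivity(igraph::make_empty_graph(4, directed = FALSE)), 0)

  for (s in 1:8) {
    g <- random_graph(n = 10 + 4 * s, p = 0.15, seed = 100 + s)
    expect_equal(natural_connectivity(g), bf_natural_connectivity(adj_of(g) * 1),
                 tolerance = 1e-9)
  }
})

test_that("global efficiency matches enumeration and the BFS oracle", {
  expect_equal(global_efficiency(igraph::make_full_graph(5)), 1)
  path3 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(global_efficiency(path3), 5 / 6, tolerance = 1e-12)
  # two disconnected edges on 4 nodes: 4 reachable ordered pairs at distance 1
  two_edges <- igraph::make_graph(c(1, 2, 3, 4), directed = FALSE)
  expect_equal(global_efficiency(two_edges), 1 / 3, tolerance = 1e-12)

  for (s in 1:8) {
    g <- random_graph(n = 12 + 3 * s, p = 0.2, seed = 200 + s)
    expect_equal(global_efficiency(g), bf_global_efficiency(adj_of(g)),
                 tolerance = 1e-12)
  }
})

test_that("average path length counts connected pairs only", {
  expect_equal(avg_path_length(igraph::make_full_graph(4)), 1)
  path3 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(avg_path_length(path3), 4 / 3, tolerance = 1e-12)
  # adding an edge never increases avgL
  ring <- igraph::make_ring(8)
  chord <- igraph::add_edges(ring, c(1, 5))
  expect_lte(avg_path_length(chord), avg_path_length(ring))
  expect_warning(out <- avg_path_length(igraph::make_empty_graph(3, directed = FALSE)),
                 "undefined")
  expect_true(is.nan(out))
  for (s in 1:5) {
    g <- random_graph(n = 15, p = 0.25, seed = 300 + s)
    expect_equal(avg_path_length(g), bf_avg_path_length(adj_of(g)),
                 tolerance = 1e-12)
  }
})

test_that("complexity indices match closed forms and the modularity oracle", {
  star <- igraph::make_star(7, mode = "undirected")
  ci_star <- complexity_indices(star)
  expect_equal(ci_star$degree_centralization, 1)
  tri <- igraph::make_full_graph(3)
  expect_equal(complexity_indices(tri)$clustering_coefficient, 1)

  # two 3-cliques joined by one edge: Q against the e_ii - a_i^2 oracle
  g <- igraph::make_graph(c(1,2, 1,3, 2,3, 4,5, 4,6, 5,6, 3,4), directed = FALSE)
  memb <- c(1, 1, 1, 2, 2, 2)
  part <- structure(list(
    membership = tibble::tibble(node = as.character(1:6), module = memb),
    sizes = tibble::tibble(module = c(1, 2), n = c(3, 3)),
    modularity = NA_real_
  ), class = "phyllonet_partition")
  igraph::V(g)$name <- as.character(1:6)
  ci <- complexity_indices(g, part)
  expect_equal(ci$modularity, bf_modularity(adj_of(g) * 1, memb),
               tolerance = 1e-12)
  expect_warning(complexity_indices(igraph::make_graph(c(1, 2), directed = FALSE)),
                 "fewer than 3 nodes")
})

test_that("ER ensembles flag departures beyond 1.96 sd", {
  # observed equal to the ensemble mean is never significant
  vals <- er_ensemble(20, 40, igraph::ecount, observed = 40, n_rep = 30,
                      seed = 5, name = "edges")
  expect_equal(vals$mean, 40)   # G(n, m) fixes the edge count
  expect_equal(vals$sd, 0)
  expect_false(vals$significant)

  # two 6-cliques joined by an edge are far more clustered than G(n, m)
  cl <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  cl <- igraph::add_edges(cl, c(1, 7))
  obs <- igraph::transitivity(cl, type = "localaverage")
  stats <- er_ensemble(igraph::vcount(cl), igraph::ecount(cl),
                       function(g) igraph::transitivity(g, type = "localaverage",
                                                        isolates = "zero"),
                       observed = obs, n_rep = 100, seed = 7,
                       name = "clustering")
  expect_true(stats$significant)
  expect_gt(obs, stats$mean + 1.96 * stats$sd)
  expect_error(er_ensemble(4, 10, igraph::ecount, observed = 1, seed = 1),
               "more edges")
})

test_that("random removal curves are seeded and decline with removal fraction", {
  g <- withr::with_seed(17, igraph::sample_gnm(60, 180))
  a <- robustness_removal(g, n_rep = 50, seed = 9)
  b <- robustness_removal(g, n_rep = 50, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(a$mean) < 0))
  expect_lt(a$mean[1], natural_connectivity(g))
  expect_error(robustness_removal(g, fractions = 1.2), "\\(0, 1\\)")
})

test_that("z-P node roles follow the participation identities and cuts", {
  # 5-clique plus a satellite: clique members have all links in-module
  g <- igraph::make_full_graph(5)
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(5, 6))
  igraph::V(g)$name <- paste0("n", 1:6)
  part <- structure(list(
    membership = tibble::tibble(node = paste0("n", 1:6),
                                module = c(1, 1, 1, 1, 1, 2)),
    sizes = tibble::tibble(module = c(1, 2), n = c(5, 1)),
    modularity = NA_real_
  ), class = "phyllonet_partition")
  roles <- zi_pi(g, part)
  expect_equal(roles$p[roles$node == "n1"], 0)
  # n5 has 4 in-module links and 1 out: P = 1 - (4/5)^2 - (1/5)^2
  expect_equal(roles$p[roles$node == "n5"], 1 - (4 / 5)^2 - (1 / 5)^2)

  # node with links split equally across two modules: P = 0.5
  h <- igraph::make_graph(c(1, 2, 1, 3), directed = FALSE)
  igraph::V(h)$name <- c("hub", "a", "b")
  part_h <- structure(list(
    membership = tibble::tibble(node = c("hub", "a", "b"),
                                module = c(1, 1, 2)),
    sizes = tibble::tibble(module = c(1, 2), n = c(2, 1)),
    modularity = NA_real_
  ), class = "phyllonet_partition")
  roles_h <- zi_pi(h, part_h)
  expect_equal(roles_h$p[roles_h$node == "hub"], 0.5)

  # role cuts: (z, P) quadrants at (2.5, 0.62)
  classify <- function(z, p) {
    dplyr::case_when(z > 2.5 & p > 0.62 ~ "kinless hub",
                     z > 2.5 ~ "provincial hub",
                     p > 0.62 ~ "connector",
                     TRUE ~ "peripheral")
  }
  expect_identical(classify(3.0, 0.5), "provincial hub")
  expect_identical(classify(3.0, 0.7), "kinless hub")
  expect_identical(classify(1.0, 0.7), "connector")
  expect_identical(classify(1.0, 0.5), "peripheral")
  # and the implementation agrees on a realistic network
  cache <- default_sim()
  rr <- zi_pi(cache$net, cache$partition)
  expect_identical(rr$role, classify(rr$z, rr$p))
  expect_true(all(rr$p >= 0 & rr$p <= 1))
})

test_that("degree tails drawn from a power law pass the KS test and classify by coverage", {
  # sample from a discrete power law (alpha = 2.5) by inverse pmf
  deg <- withr::with_seed(41, {
    k <- 1:10000
    sample(k, 500, replace = TRUE, prob = k^(-2.5))
  })
  fit_large <- tail_powerlaw(deg, n_boot = 100, seed = 2)
  expect_gt(fit_large$ks_pvalue, 0.05)
  expect_equal(fit_large$exponent, 2.5, tolerance = 0.25)
  expect_identical(fit_large$sf_class, ifelse(fit_large$n_covered > 50,
                                              "weak", "weakest"))

  deg_small <- withr::with_seed(43, {
    k <- 1:10000
    sample(k, 38, replace = TRUE, prob = k^(-2.5))
  })
  fit_small <- tail_powerlaw(deg_small, n_boot = 100, seed = 2)
  expect_gt(fit_small$ks_pvalue, 0.05)
  expect_lte(fit_small$n_covered, 50)
  expect_identical(fit_small$sf_class, "weakest")

  flat <- tail_powerlaw(rep(4L, 30))
  expect_identical(flat$sf_class, "not")
  expect_true(is.nan(flat$ks_pvalue))
})
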