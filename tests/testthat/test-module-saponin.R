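test_that("fast-greedy detection splits cliques and respects components", {
  # two 4-cliques joined by one edge
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- paste0("n", 1:8)
  part <- detect_modules(g)
  memb <- setNames(part$membership$module, part$membership$node)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("n", 1:4)])), 1)
  expect_equal(length(unique(memb[paste0("n", 5:8)])), 1)

  # the split matches the brute-force maximum-modularity partition
  best_q <- max(vapply(bf_partitions(8), function(p) {
    m <- integer(8)
    for (i in seq_along(p)) m[p[[i]]] <- i
    bf_modularity(adj_of(g) * 1, m)
  }, numeric(1)))
  expect_equal(part$modularity, best_q, tolerance = 1e-12)

  # disconnected components never share a module
  h <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  igraph::V(h)$name <- paste0("m", 1:6)
  ph <- detect_modules(h)
  mh <- setNames(ph$membership$module, ph$membership$node)
  expect_false(any(mh[paste0("m", 1:3)] %in% mh[paste0("m", 4:6)]))

  # determinism
  expect_identical(detect_modules(g)$membership, part$membership)
})

test_that("greedy modularity never beats the exhaustive optimum on small graphs", {
  for (s in 1:5) {
    g <- random_graph(n = 8, p = 0.35, seed = 400 + s)
    if (igraph::ecount(g) == 0) next
    part <- detect_modules(g)
    best_q <- max(vapply(bf_partitions(8), function(p) {
      m <- integer(8)
      for (i in seq_along(p)) m[p[[i]]] <- i
      bf_modularity(adj_of(g) * 1, m)
    }, numeric(1)))
    expect_lte(part$modularity, best_q + 1e-12)
  }
})

test_that("module eigengenes summarise a rank-1 module exactly", {
  withr::with_seed(61, {
    n <- 20
    x <- exp(rnorm(n))
    coefs <- c(2, 3, 5, 7, 11)
    members <- sapply(coefs, function(cc) cc * x)
    colnames(members) <- paste0("M", 1:5)
    other <- matrix(rpois(n * 3, 50), n, dimnames = list(NULL, paste0("O", 1:3)))
    ab <- dplyr::bind_cols(tibble::tibble(sample_id = paste0("S", 1:n)),
                           tibble::as_tibble(cbind(members, other)))
  })
  eg <- module_eigengene(ab, paste0("M", 1:5))
  expect_equal(eg$var_explained, 1, tolerance = 1e-10)
  # eigengene equals the (standardised) shared profile up to orientation
  rel <- as.matrix(ab[paste0("M", 1:5)]) / rowSums(as.matrix(ab[-1]))
  prof <- scale(rel[, 1])[, 1]
  expect_equal(abs(cor(eg$scores, prof)), 1, tolerance = 1e-10)
  expect_gte(cor(eg$scores, prof), 0)   # orientation rule

  # invariance under member reordering
  eg2 <- module_eigengene(ab, paste0("M", c(4, 2, 5, 1, 3)))
  expect_equal(eg$scores, eg2$scores, tolerance = 1e-9)

  expect_error(module_eigengene(ab, paste0("M", 1:4)), "5 or more")
})

test_that("eigengene computation matches an SVD oracle and tracks planted factors", {
  cache <- default_sim()
  eg <- module_eigengenes(cache$partition, cache$abund)
  # oracle: direct SVD of the z-scored relative-abundance submatrix
  mod <- cache$partition$sizes$module[which.max(cache$partition$sizes$n)]
  members <- cache$partition$membership$node[
    cache$partition$membership$module == mod]
  m <- as.matrix(cache$abund[-1])
  rownames(m) <- cache$abund$sample_id
  z <- scale(m[, members] / rowSums(m))
  sv <- svd(z)
  oracle <- sv$u[, 1] * sv$d[1]
  if (cor(oracle, rowMeans(z)) < 0) oracle <- -oracle
  expect_equal(unname(eg$scores[[paste0("M", mod)]]), unname(oracle),
               tolerance = 1e-8)

  # a low-noise planted module's eigengene tracks its latent factor
  cfg <- sim_config(n_samples = 60, n_asvs = 40, module_sizes = c(10),
                    within_module_rho = 0.9, noise_sd = 0.2,
                    n_env_pairs = 0, n_dispersal_asvs = 0, seed = 15)
  sim <- simulate_community(cfg)
  truth <- sim$truth
  planted1 <- names(truth$module_of_asv)[!is.na(truth$module_of_asv)]
  eg1 <- module_eigengene(sim$abundance, planted1)
  expect_gt(abs(cor(eg1$scores, truth$module_factors[, 1])), 0.95)
})

test_that("saponin PCA is covariance-based with row-sum totals", {
  withr::with_seed(62, {
    n <- 8
    base <- exp(rnorm(n))
    sap1 <- tibble::tibble(sample_id = paste0("S", 1:n),
                           A = 2 * base, B = 5 * base, C = 0.5 * base)
  })
  s1 <- saponin_pca(sap1)
  expect_equal(s1$var_explained, 1, tolerance = 1e-10)
  expect_equal(unname(s1$total), unname(rowSums(sap1[-1])))

  withr::with_seed(63, {
    sap2 <- dplyr::bind_cols(
      tibble::tibble(sample_id = paste0("S", 1:10)),
      tibble::as_tibble(matrix(rexp(80), 10,
                               dimnames = list(NULL, paste0("sap", 1:8))))
    )
  })
  s2 <- saponin_pca(sap2)
  ev <- eigen(cov(as.matrix(sap2[-1])), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(s2$var_explained, ev[1] / sum(ev), tolerance = 1e-10)
  expect_equal(sum(s2$var_fractions), 1, tolerance = 1e-12)

  # no scaling: inflating one column's units changes the loadings
  sap3 <- sap2
  sap3$sap1 <- sap3$sap1 * 10
  s3 <- saponin_pca(sap3)
  corr_pca <- prcomp(as.matrix(sap2[-1]), center = TRUE, scale. = TRUE)
  expect_false(isTRUE(all.equal(abs(s3$loadings), abs(s2$loadings),
                                tolerance = 1e-6)))
  expect_false(isTRUE(all.equal(abs(s3$loadings),
                                abs(corr_pca$rotation[, 1]), tolerance = 1e-6)))
})

test_that("collinearity filtering removes redundant variables only", {
  withr::with_seed(64, {
    n <- 25
    a <- rnorm(n)
    env <- tibble::tibble(sample_id = paste0("S", 1:n),
                          a = a, a_copy = a, b = rnorm(n), c = rnorm(n))
  })
  out <- collinearity_filter(env)
  vars <- setdiff(names(out), "sample_id")
  expect_length(vars, 3)
  expect_true(xor("a" %in% vars, "a_copy" %in% vars))
  r2 <- cor(as.matrix(out[vars]), method = "spearman")^2
  diag(r2) <- 0
  expect_lte(max(r2), 0.6)

  # independent variables are untouched
  env_ind <- env[c("sample_id", "a", "b", "c")]
  expect_identical(collinearity_filter(env_ind), env_ind)
})

test_that("candidate screening flags true associations and respects the FDR cut", {
  withr::with_seed(65, {
    n <- 200
    pc1 <- rnorm(n)
    eig <- tibble::tibble(sample_id = paste0("S", 1:n),
                          M1 = pc1,                 # identical to the response
                          M2 = rnorm(n))            # pure noise
    env <- tibble::tibble(sample_id = eig$sample_id, pH = rnorm(n))
  })
  sap <- list(pc1 = setNames(pc1, eig$sample_id))
  out <- screen_candidates(eig, env, sap)
  expect_true(out$candidate[out$variable == "M1"])
  expect_equal(out$rho[out$variable == "M1"], 1)
  expect_false(out$candidate[out$variable == "M2"])
  # tightening the cut can only shrink the candidate set
  strict <- screen_candidates(eig, env, sap, fdr = 1e-6)
  expect_true(all(strict$variable[strict$candidate] %in%
                    out$variable[out$candidate]))
})

test_that("cross-validated learners behave sanely under shared folds", {
  withr::with_seed(66, {
    n <- 60
    y <- rnorm(n)
    feats <- list(
      leak = tibble::tibble(y_copy = y),             # response as a feature
      noise = tibble::tibble(z = rnorm(n))
    )
  })
  out <- ml_compare(feats, y, k_folds = 5, seed = 2, knn_k = 1)
  expect_true(all(out$spearman_rho >= -1 & out$spearman_rho <= 1, na.rm = TRUE))
  knn_leak <- out$mse[out$model == "leak" & out$learner == "KNN"]
  expect_lt(knn_leak, 0.05)
  expect_lt(knn_leak, out$mse[out$model == "noise" & out$learner == "KNN"])

  # identical seed reproduces identical scores (shared fold assignment)
  out2 <- ml_compare(feats, y, k_folds = 5, seed = 2, knn_k = 1)
  expect_identical(out, out2)

  expect_warning(
    ml_compare(c(feats, list(empty = tibble::tibble())), y, seed = 2),
    "skipped")
})
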