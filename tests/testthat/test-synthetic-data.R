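test_that("generator is seed-deterministic and rarefies every sample to depth", {
  cfg <- sim_config(n_samples = 8, n_asvs = 40, module_sizes = c(10, 8),
                    seed = 11)
  a <- simulate_community(cfg)
  b <- simulate_community(cfg)
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$env, b$env)
  expect_identical(a$coords, b$coords)

  counts <- as.matrix(a$abundance[-1])
  expect_true(all(rowSums(counts) == cfg$rarefaction_depth))
  expect_true(all(counts >= 0))
  expect_true(all(counts == floor(counts)))
})

test_that("default depth matches the rarefaction target of 12,412 reads", {
  sim <- default_sim()$sim
  expect_true(all(rowSums(as.matrix(sim$abundance[-1])) == 12412))
})

test_that("planted modules produce stronger within- than between-module correlation", {
  cfg <- sim_config(n_samples = 40, n_asvs = 30, module_sizes = c(10, 10),
                    within_module_rho = 0.9, noise_sd = 0.1,
                    n_env_pairs = 0, n_dispersal_asvs = 0, seed = 2)
  sim <- simulate_community(cfg)
  m <- as.matrix(sim$abundance[-1])
  rho <- abs(cor(m, method = "spearman"))
  mod <- sim$truth$module_of_asv[colnames(m)]
  same <- outer(mod, mod, "==") & !is.na(outer(mod, mod, "=="))
  up <- upper.tri(rho)
  both_mod <- outer(!is.na(mod), !is.na(mod), "&")
  expect_gt(median(rho[up & same]), median(rho[up & !same & both_mod]))
})

test_that("raising the noise level weakens within-module correlation on average", {
  med_within <- function(noise, seed) {
    cfg <- sim_config(n_samples = 30, n_asvs = 24, module_sizes = c(12),
                      noise_sd = noise, n_env_pairs = 0,
                      n_dispersal_asvs = 0, seed = seed)
    sim <- simulate_community(cfg)
    m <- as.matrix(sim$abundance[-1])
    mod <- sim$truth$module_of_asv[colnames(m)]
    rho <- abs(cor(m, method = "spearman"))
    up <- upper.tri(rho)
    same <- outer(mod, mod, "==")
    same[is.na(same)] <- FALSE
    median(rho[up & same])
  }
  seeds <- 1:4
  lo <- mean(vapply(seeds, function(s) med_within(0.3, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) med_within(1.5, s), numeric(1)))
  expect_gt(lo, hi)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(n_asvs = 10, module_sizes = c(8, 8)), "module_sizes")
  expect_error(sim_config(module_sizes = c(10, 10), prm_modules = 3),
               "prm_modules")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
})

test_that("saponins track the planted module factor", {
  # noiseless, single PRM, no environmental contribution: total saponin is a
  # strictly monotone map of the module factor
  cfg <- sim_config(n_samples = 20, n_asvs = 30, module_sizes = c(10, 10),
                    prm_modules = 1, noise_sd = 1e-6, saponin_env_effect = 0,
                    n_env_pairs = 0, n_dispersal_asvs = 0, seed = 4)
  sim <- simulate_community(cfg)
  sap <- simulate_saponins(sim, cfg)
  expect_identical(setdiff(names(sap), "sample_id"),
                   c("Rb1", "Rb2", "Rc", "Rd", "Re", "Rg1", "F1", "R1"))
  total <- rowSums(sap[-1])
  expect_equal(cor(total, sim$truth$module_factors[, 1], method = "spearman"), 1)

  # realistic noise, planted effect 0.8, n = 200: association clearly present
  cfg2 <- sim_config(n_samples = 200, n_asvs = 30, module_sizes = c(10, 10),
                     prm_modules = 1, prm_effect_size = 0.8,
                     n_env_pairs = 0, n_dispersal_asvs = 0, seed = 5)
  sim2 <- simulate_community(cfg2)
  sap2 <- simulate_saponins(sim2, cfg2)
  rho <- cor(rowSums(sap2[-1]), sim2$truth$module_factors[, 1],
             method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("zero planted saponin effect warns that the signal is absent", {
  cfg <- sim_config(n_samples = 10, n_asvs = 30, module_sizes = c(10, 10),
                    prm_effect_size = 0, n_env_pairs = 0,
                    n_dispersal_asvs = 0, seed = 6)
  sim <- simulate_community(cfg)
  expect_warning(simulate_saponins(sim, cfg), "signal is absent")
})

test_that("taxonomy lineages are 7-rank, prefix-consistent, and seeded", {
  tg <- simulate_taxonomy_guilds(50, seed = 3)
  expect_identical(names(tg$taxonomy),
                   c("asv_id", "kingdom", "phylum", "class", "order",
                     "family", "genus", "species"))
  # same genus implies same family (and up the ranks by transitivity)
  by_genus <- split(tg$taxonomy$family, tg$taxonomy$genus)
  expect_true(all(vapply(by_genus, function(x) length(unique(x)) == 1,
                         logical(1))))
  by_family <- split(tg$taxonomy$order, tg$taxonomy$family)
  expect_true(all(vapply(by_family, function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_identical(tg, simulate_taxonomy_guilds(50, seed = 3))

  degenerate <- simulate_taxonomy_guilds(
    20, guild_probs = c(plant_pathogen = 0, endophyte = 1, epiphyte = 0,
                        saprotroph = 0, unassigned = 0), seed = 1)
  expect_true(all(degenerate$guilds$guild == "endophyte"))
  expect_error(simulate_taxonomy_guilds(5, orders = character(0)), "non-empty")
})

test_that("fast-greedy modules on a low-noise draw recover the planted partition", {
  cache <- default_sim()
  truth <- cache$sim$truth$module_of_asv
  part <- cache$partition
  nodes <- intersect(part$membership$node, names(truth)[!is.na(truth)])
  detected <- part$membership$module[match(nodes, part$membership$node)]
  expect_gte(bf_ari(detected, truth[nodes]), 0.9)
})
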