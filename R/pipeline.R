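#' Run the full analysis pipeline on a synthetic community
#'
#' Orchestrates every stage from one configuration: simulate the community,
#' build the RMT-thresholded co-occurrence network, characterise topology
#' and robustness against Erdős–Rényi ensembles, attribute links, detect
#' modules and screen them against saponin profiles with paired ML
#' learners, identify positive regulation modules (degree, guilds,
#' stochasticity ratio, path model), extract positive regulation taxa and
#' test order enrichment.  Each stage writes TSV/JSON outputs under
#' `out_dir` and consumes only written files plus its stage inputs, and a
#' manifest with file hashes and derived seeds makes reruns verifiable:
#' identical config and seed reproduce identical hashes.
#'
#' @param config A [sim_config()] object (its `seed` is the master seed).
#' @param out_dir Output directory.
#' @param rmt_grid List with `t_min`, `t_max`, `step` for [rmt_scan()].
#' @param n_rep Random-graph ensemble size and removal replicates
#'   (default 100).
#' @param removal_fractions Node-removal fractions (default 0.2, 0.3, 0.4).
#' @param n_rand Stochasticity-ratio randomisations (default 200).
#' @param mantel_perm Mantel permutations for link attribution
#'   (default 199).
#' @param fdr FDR level used throughout (default 0.05).
#' @return Invisibly, a list with every stage result plus the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         rmt_grid = list(t_min = 0.3, t_max = 0.95, step = 0.02),
                         n_rep = 100,
                         removal_fractions = c(0.2, 0.3, 0.4),
                         n_rand = 200,
                         mantel_perm = 199,
                         fdr = 0.05) {
  stopifnot(inherits(config, "phyllonet_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  wr <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)

  # --- simulate -------------------------------------------------------
  res <- list()
  stage("simulate", {
    res$sim <- simulate_community(config)
    res$saponins <- simulate_saponins(res$sim, config)
    res$taxonomy_guilds <- simulate_taxonomy_guilds(
      config$n_asvs, seed = derive_seed(seed, "taxonomy"))
    write_simulation(res$sim, res$saponins, res$taxonomy_guilds,
                     file.path(out_dir, "sim"))
  })

  # --- network --------------------------------------------------------
  stage("network", {
    abund <- read_abundance(file.path(out_dir, "sim", "abundance.tsv"))
    res$abund_filtered <- abundance_filter(abund)
    res$corr <- spearman_matrix(res$abund_filtered)
    res$scan <- rmt_scan(res$corr, t_min = rmt_grid$t_min,
                         t_max = rmt_grid$t_max, step = rmt_grid$step,
                         fdr = fdr)
    res$threshold <- select_transition(res$scan)
    res$net <- build_network(res$corr, res$threshold, fdr = fdr)
    write_network(res$net, file.path(out_dir, "network"))
    wr(res$scan, "network/rmt_scan.tsv")
  })

  # --- topology -------------------------------------------------------
  stage("topology", {
    res$partition <- detect_modules(res$net)
    res$topology <- complexity_indices(res$net, res$partition)
    res$ensembles <- ensemble_panel(res$net, n_rep = n_rep,
                                    seed = derive_seed(seed, "ensemble"))
    res$removal <- robustness_removal(res$net, removal_fractions,
                                      n_rep = n_rep,
                                      seed = derive_seed(seed, "removal"))
    res$roles <- zi_pi(res$net, res$partition)
    res$tail <- tail_powerlaw(res$net)
    wr(res$topology, "topology_summary.tsv")
    wr(res$ensembles, "ensemble_stats.tsv")
    wr(res$removal, "removal_curves.tsv")
    wr(res$roles, "node_roles.tsv")
    wr(res$tail, "tail_fit.tsv")
  })

  # --- link attribution ----------------------------------------------
  stage("lted", {
    res$lted <- attribute_links(res$net, res$abund_filtered, res$sim$env,
                                res$sim$coords, n_perm = mantel_perm,
                                seed = derive_seed(seed, "lted"), fdr = fdr)
    wr(res$lted$edges, "link_attribution.tsv")
    wr(res$lted$proportions, "attribution_summary.tsv")
  })

  # --- modules & saponins --------------------------------------------
  stage("modules", {
    res$eigengenes <- module_eigengenes(res$partition, res$abund_filtered)
    res$sap_summary <- saponin_pca(res$saponins)
    env_t <- collinearity_filter(log_transform_env(res$sim$env))
    res$env_filtered <- env_t
    res$candidates <- screen_candidates(res$eigengenes$scores, env_t,
                                        res$sap_summary, fdr = fdr)
    cand_mods <- res$candidates$variable[res$candidates$candidate &
                                           res$candidates$family == "module"]
    cand_env <- res$candidates$variable[res$candidates$candidate &
                                          res$candidates$family == "environment"]
    if (length(cand_env) == 0) cand_env <- setdiff(names(env_t), "sample_id")
    eig_cand <- res$eigengenes$scores[c("sample_id",
                                        intersect(names(res$eigengenes$scores),
                                                  cand_mods))]
    fsets <- ml_feature_sets(env_t[c("sample_id", cand_env)], eig_le = eig_cand)
    res$ml <- ml_compare(
      Filter(Negate(is.null), fsets),
      response = as.numeric(res$sap_summary$pc1),
      seed = derive_seed(seed, "ml"))
    wr(tidy(res$partition), "modules.tsv")
    wr(res$eigengenes$scores, "eigengenes.tsv")
    wr(res$candidates, "candidates.tsv")
    wr(res$ml, "ml_scores.tsv")
  })

  # --- PRM / NST / SEM ------------------------------------------------
  stage("prm", {
    cand_mods <- res$candidates$variable[res$candidates$candidate &
                                           res$candidates$family == "module"]
    cand_ids <- as.integer(sub("^M", "", cand_mods))
    if (length(cand_ids) == 0) cand_ids <- NULL
    res$prm <- identify_prm(res$partition, res$abund_filtered,
                            res$sap_summary$total,
                            candidate_modules = cand_ids, fdr = fdr)
    prm_ids <- res$prm$modules$module[res$prm$modules$is_prm]
    prm_nodes <- res$prm$members$node[res$prm$members$module %in% prm_ids]
    other_nodes <- setdiff(network_nodes(res$net), prm_nodes)
    if (length(prm_nodes) && length(other_nodes)) {
      res$degree_cmp <- degree_compare(prm_nodes, other_nodes, res$net)
      res$guilds_prm <- guild_composition(prm_nodes, res$taxonomy_guilds$guilds)
      res$guilds_other <- guild_composition(other_nodes,
                                            res$taxonomy_guilds$guilds)
      res$nst <- nst_contrast(res$abund_filtered, prm_nodes, other_nodes,
                              n_rand = n_rand,
                              seed = derive_seed(seed, "nst"))
      wr(res$degree_cmp, "degree_compare.tsv")
      wr(res$nst, "nst_results.tsv")
    }
    if (length(prm_ids)) {
      cand_env <- res$candidates$variable[res$candidates$candidate &
                                            res$candidates$family == "environment"]
      if (length(cand_env) == 0) {
        cand_env <- setdiff(names(res$env_filtered), "sample_id")[1]
      }
      sem_data <- dplyr::bind_cols(
        res$env_filtered[cand_env],
        res$eigengenes$scores[paste0("M", prm_ids)],
        tibble(total_saponin = as.numeric(res$sap_summary$total))
      )
      model <- c(
        paste0("M", prm_ids, " ~ ", paste(cand_env, collapse = " + ")),
        paste0("total_saponin ~ ", paste(c(cand_env, paste0("M", prm_ids)),
                                         collapse = " + "))
      )
      res$sem <- fit_path_model(sem_data, model)
      jsonlite::write_json(
        list(paths = res$sem$paths, chi2 = res$sem$chi2, df = res$sem$df,
             chi2_p = res$sem$chi2_p, cfi = res$sem$cfi,
             rmsea = res$sem$rmsea),
        file.path(out_dir, "sem_fit.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
      sem_ok <- dplyr::filter(res$sem$paths,
                              .data$lhs == "total_saponin",
                              grepl("^M", .data$rhs),
                              !is.na(.data$p_value), .data$p_value < 0.05,
                              .data$estimate > 0)
      validated <- as.integer(sub("^M", "", sem_ok$rhs))
      if (length(validated) == 0) validated <- prm_ids
      res$prt <- identify_prt(res$prm, modules = validated, fdr = fdr)
      wr(tibble(node = res$prt), "prt.tsv")
    } else {
      res$prt <- character(0)
    }
    wr(res$prm$modules, "prm_results.tsv")
  })

  # --- enrichment & taxonomy -----------------------------------------
  stage("enrichment", {
    res$enrichment <- order_enrichment(res$prt, network_nodes(res$net),
                                       res$taxonomy_guilds$taxonomy, fdr = fdr)
    res$tree <- taxonomy_tree(res$taxonomy_guilds$taxonomy)
    ape::write.tree(res$tree, file.path(out_dir, "tree.nwk"))
    wr(res$enrichment, "enrichment.tsv")
  })

  # --- recovery report & manifest ------------------------------------
  stage("report", {
    res$recovery <- prm_recovery(res$prm, res$partition, res$sim$truth)
    wr(res$recovery, "recovery_report.tsv")
    files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
    files <- files[basename(files) != "run_manifest.json"]
    res$manifest <- list(
      package_version = as.character(utils::packageVersion("phyllonet")),
      master_seed = seed,
      threshold = res$threshold,
      hashes = as.list(setNames(unname(tools::md5sum(files)),
                                sub(paste0("^", out_dir, "/?"), "", files)))
    )
    jsonlite::write_json(res$manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(res)
}

#' Compare detected PRMs against the planted ground truth
#'
#' Maps each detected module to the planted module contributing most of its
#' members, then scores the detected PRM set against the planted PRM ids.
#'
#' @param prm A [identify_prm()] result.
#' @param partition The [detect_modules()] partition used.
#' @param truth The generator's `phyllonet_truth`.
#' @return One-row tibble: `n_planted`, `n_detected`, `precision`,
#'   `recall`.
#' @export
prm_recovery <- function(prm, partition, truth) {
  map_detected <- function(mod) {
    members <- partition$membership$node[partition$membership$module == mod]
    planted <- truth$module_of_asv[members]
    planted <- planted[!is.na(planted)]
    if (length(planted) == 0) return(NA_integer_)
    as.integer(names(which.max(table(planted))))
  }
  detected <- prm$modules$module[prm$modules$is_prm]
  detected_planted <- unique(na.omit(vapply(detected, map_detected, integer(1))))
  planted <- truth$planted_prms
  tp <- length(intersect(detected_planted, planted))
  tibble(
    n_planted = length(planted),
    n_detected = length(detected_planted),
    precision = if (length(detected_planted)) tp / length(detected_planted) else NA_real_,
    recall = if (length(planted)) tp / length(planted) else NA_real_
  )
}
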