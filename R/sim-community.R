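#' Configuration for the synthetic phyllosphere community generator
#'
#' Bundles every knob of the synthetic-data generator.  The defaults mirror
#' the study scale the package targets: 27 samples per plant
#' species x compartment, a rarefaction depth of 12,412 reads, a modular
#' community with a handful of environmentally driven and dispersal-limited
#' taxa, and eight leaf saponins driven by one positive regulation module.
#'
#' Modules are numbered `1..n_modules`; ASVs `1..sum(module_sizes)` belong to
#' the modules in order, the remaining ASVs are background.  Environmentally
#' driven pairs and dispersal-limited ASVs are carved out of the background
#' block so they do not interfere with planted module structure.
#'
#' @param n_samples Number of samples (default 27).
#' @param n_asvs Total number of ASVs.
#' @param module_sizes Integer vector of planted module sizes; their sum must
#'   not exceed `n_asvs`.
#' @param within_module_rho Target pairwise correlation of log-abundances
#'   within a module, in (0, 1).
#' @param n_env_factors Number of edaphic variables to simulate.
#' @param n_env_pairs Number of ASV pairs co-driven by a shared environmental
#'   factor (cycled over the factors).
#' @param n_dispersal_asvs Number of ASVs whose abundance decays with
#'   distance from a shared focal point.
#' @param distance_decay_rate Exponential decay rate (per unit distance on
#'   the unit square) of dispersal-limited abundance.
#' @param n_saponins Number of saponin columns (default 8: Rb1, Rb2, Rc, Rd,
#'   Re, Rg1, F1, R1).
#' @param prm_modules Module ids (1-based) planted as positive regulation
#'   modules of total saponin.
#' @param prm_effect_size Standardised effect of each PRM factor on every
#'   log-saponin.
#' @param saponin_env_effect Standardised effect of the first environmental
#'   factor on every log-saponin (0 removes the environmental signal).
#' @param noise_sd Standard deviation of the Gaussian noise added to
#'   log-abundances and log-saponins.
#' @param rarefaction_depth Reads retained per sample after rarefaction.
#' @param seed Integer seed; the same seed reproduces the tables byte for
#'   byte.
#' @return A list of class `phyllonet_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$rarefaction_depth
sim_config <- function(n_samples = 27,
                       n_asvs = 120,
                       module_sizes = c(25, 25, 20, 15),
                       within_module_rho = 0.7,
                       n_env_factors = 5,
                       n_env_pairs = 5,
                       n_dispersal_asvs = 8,
                       distance_decay_rate = 2,
                       n_saponins = 8,
                       prm_modules = 1L,
                       prm_effect_size = 0.8,
                       saponin_env_effect = 0.3,
                       noise_sd = 0.5,
                       rarefaction_depth = 12412,
                       seed = 1L) {
  if (sum(module_sizes) > n_asvs) {
    abort("sum(module_sizes) exceeds n_asvs")
  }
  n_modules <- length(module_sizes)
  if (length(prm_modules) && !all(prm_modules %in% seq_len(n_modules))) {
    abort("prm_modules must be module ids in 1..length(module_sizes)")
  }
  if (rarefaction_depth <= 0) abort("rarefaction_depth must be positive")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (within_module_rho <= 0 || within_module_rho >= 1) {
    abort("within_module_rho must lie in (0, 1)")
  }
  n_background <- n_asvs - sum(module_sizes)
  if (2 * n_env_pairs + n_dispersal_asvs > n_background) {
    abort("not enough background ASVs for env pairs and dispersal ASVs")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_asvs = as.integer(n_asvs),
      n_modules = n_modules, module_sizes = as.integer(module_sizes),
      within_module_rho = within_module_rho,
      n_env_factors = as.integer(n_env_factors),
      n_env_pairs = as.integer(n_env_pairs),
      n_dispersal_asvs = as.integer(n_dispersal_asvs),
      distance_decay_rate = distance_decay_rate,
      n_saponins = as.integer(n_saponins),
      prm_modules = as.integer(prm_modules),
      prm_effect_size = prm_effect_size,
      saponin_env_effect = saponin_env_effect,
      noise_sd = noise_sd,
      rarefaction_depth = as.integer(rarefaction_depth),
      seed = as.integer(seed)
    ),
    class = "phyllonet_config"
  )
}

# rarefy one count vector to `depth` reads without replacement
rarefy_counts <- function(counts, depth) {
  total <- sum(counts)
  if (total < depth) abort("sample has fewer reads than the rarefaction depth")
  reads <- sample(rep.int(seq_along(counts), counts), depth, replace = FALSE)
  tabulate(reads, nbins = length(counts))
}

saponin_names <- function(n) {
  base <- c("Rb1", "Rb2", "Rc", "Rd", "Re", "Rg1", "F1", "R1")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("Sap", seq_len(n - length(base))))
}

edaphic_names <- function(n) {
  base <- c("pH", "OC", "TN", "NIN", "AMN", "AP", "AK", "ECa", "EMg", "AS", "MC")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("Env", seq_len(n - length(base))))
}

#' Simulate a modular phyllosphere community with planted structure
#'
#' Generates a rarefied ASV count table together with per-sample edaphic
#' variables, spatial coordinates, and the ground truth needed for recovery
#' tests.  Latent Gaussian module factors are drawn per sample; member ASV
#' log-abundances load on their module factor so that pairs within a module
#' reach the configured Spearman correlation.  Environmentally driven ASV
#' pairs additionally load on a shared edaphic factor; dispersal-limited
#' ASVs decay exponentially with distance from a focal plantation on the
#' unit square.  Counts are drawn multinomially per sample (3x depth) and
#' rarefied without replacement to exactly `rarefaction_depth` reads.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `phyllonet_sim` with elements `abundance`
#'   (tibble, `sample_id` + integer ASV columns), `env` (tibble of edaphic
#'   variables), `coords` (tibble `sample_id`, `x`, `y`), and `truth`
#'   (class `phyllonet_truth`: `module_of_asv`, `planted_prms`,
#'   `planted_env_links`, `planted_dispersal_links`, `module_factors`,
#'   `path_coefficients`).
#' @export
#' @examples
#' sim <- simulate_community(sim_config(n_samples = 10, seed = 1))
#' rowSums(sim$abundance[-1])
simulate_community <- function(config) {
  stopifnot(inherits(config, "phyllonet_config"))
  withr::with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_asvs
    asv_ids <- sprintf("ASV_%03d", seq_len(p))
    sample_ids <- sprintf("S%02d", seq_len(n))

    module_of_asv <- rep(NA_integer_, p)
    idx <- 1L
    for (m in seq_len(config$n_modules)) {
      module_of_asv[idx:(idx + config$module_sizes[m] - 1L)] <- m
      idx <- idx + config$module_sizes[m]
    }
    background <- which(is.na(module_of_asv))

    # latent factors: one per module, one per edaphic variable
    f_mod <- matrix(rnorm(n * config$n_modules), n, config$n_modules)
    f_env <- matrix(rnorm(n * config$n_env_factors), n, config$n_env_factors)

    rho <- config$within_module_rho
    loading <- config$noise_sd * sqrt(rho / (1 - rho))

    base <- rnorm(p, 0, 0.7)                      # per-ASV log-mean offsets
    logab <- matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    logab <- sweep(logab, 2, base, "+")
    for (m in seq_len(config$n_modules)) {
      members <- which(module_of_asv == m)
      logab[, members] <- logab[, members] + loading * f_mod[, m]
    }

    # environmentally driven pairs, carved from the background block
    env_links <- tibble(asv_i = character(), asv_j = character(), env = character())
    take <- 0L
    if (config$n_env_pairs > 0) {
      for (k in seq_len(config$n_env_pairs)) {
        i <- background[take + 1L]; j <- background[take + 2L]; take <- take + 2L
        e <- ((k - 1L) %% config$n_env_factors) + 1L
        logab[, c(i, j)] <- logab[, c(i, j)] + loading * f_env[, e]
        env_links <- dplyr::bind_rows(env_links, tibble(
          asv_i = asv_ids[i], asv_j = asv_ids[j], env = edaphic_names(config$n_env_factors)[e]
        ))
      }
    }

    # sampling layout mirrors the field design: three plantations (tight
    # clusters of plots) placed on the unit square
    centers <- cbind(runif(3), runif(3))
    plantation <- rep_len(1:3, n)
    coords <- tibble(
      sample_id = sample_ids,
      x = centers[plantation, 1] + rnorm(n, 0, 0.03),
      y = centers[plantation, 2] + rnorm(n, 0, 0.03)
    )

    # dispersal-limited ASVs: exponential decay with distance from a source
    # plantation, so between-plantation distance drives their turnover
    dispersal_idx <- integer(0)
    disp_links <- tibble(asv_i = character(), asv_j = character())
    if (config$n_dispersal_asvs > 0) {
      dispersal_idx <- background[take + seq_len(config$n_dispersal_asvs)]
      focal <- centers[sample.int(3, 1), ]
      d <- sqrt((coords$x - focal[1])^2 + (coords$y - focal[2])^2)
      decay <- -config$distance_decay_rate * d
      # dispersal signal replaces most of the iid noise so the spatial
      # gradient dominates these ASVs' profiles
      logab[, dispersal_idx] <-
        matrix(rnorm(n * length(dispersal_idx), 0, 0.2 * config$noise_sd),
               n, length(dispersal_idx)) +
        matrix(base[dispersal_idx], n, length(dispersal_idx), byrow = TRUE) +
        3 * decay
      pairs <- t(combn(dispersal_idx, 2))
      disp_links <- tibble(asv_i = asv_ids[pairs[, 1]], asv_j = asv_ids[pairs[, 2]])
    }

    # multinomial sequencing then rarefaction without replacement
    depth <- config$rarefaction_depth
    probs <- exp(logab)
    counts <- matrix(0L, n, p, dimnames = list(sample_ids, asv_ids))
    for (s in seq_len(n)) {
      raw <- as.integer(rmultinom(1, 3L * depth, probs[s, ]))
      counts[s, ] <- rarefy_counts(raw, depth)
    }

    env_tbl <- dplyr::bind_cols(
      tibble(sample_id = sample_ids),
      as_tibble(`colnames<-`(f_env, edaphic_names(config$n_env_factors)))
    )
    # edaphic variables on plausible scales (pH around 6, others log-normal);
    # monotone transforms leave the Spearman machinery untouched
    nm <- edaphic_names(config$n_env_factors)
    for (k in seq_along(nm)) {
      env_tbl[[nm[k]]] <- if (nm[k] == "pH") 6 + 0.5 * f_env[, k] else exp(1 + 0.8 * f_env[, k])
    }

    truth <- structure(
      list(
        module_of_asv = setNames(module_of_asv, asv_ids),
        planted_prms = config$prm_modules,
        planted_env_links = env_links,
        planted_dispersal_links = disp_links,
        dispersal_asvs = asv_ids[dispersal_idx],
        module_factors = `colnames<-`(f_mod, paste0("M", seq_len(config$n_modules))),
        env_factors = `colnames<-`(f_env, edaphic_names(config$n_env_factors)),
        path_coefficients = list(prm_to_saponin = config$prm_effect_size,
                                 env_to_saponin = config$saponin_env_effect)
      ),
      class = "phyllonet_truth"
    )

    list(
      abundance = matrix_abund(counts),
      env = env_tbl,
      coords = coords,
      truth = truth
    )
  })
}

#' Simulate leaf saponin contents driven by planted modules
#'
#' Each log-saponin is a linear combination of the planted positive
#' regulation module factors (`prm_effect_size` each), the first edaphic
#' factor (`saponin_env_effect`), and Gaussian noise; contents are
#' exponentiated so they live on a positive mg/g-like scale.  Columns are
#' named after the eight study saponins (ginsenosides Rb1, Rb2, Rc, Rd, Re,
#' Rg1, F1 and notoginsenoside R1).
#'
#' @param sim Output of [simulate_community()].
#' @param config The same [sim_config()] used to generate `sim`.
#' @return A tibble with `sample_id` and one column per saponin.
#' @export
simulate_saponins <- function(sim, config) {
  stopifnot(inherits(config, "phyllonet_config"))
  truth <- sim$truth
  if (config$prm_effect_size == 0 && length(truth$planted_prms)) {
    warn("prm_effect_size is 0: planted module->saponin signal is absent")
  }
  withr::with_seed(derive_seed(config$seed, "saponins"), {
    n <- nrow(sim$abundance)
    prm_signal <- if (length(truth$planted_prms)) {
      rowSums(truth$module_factors[, truth$planted_prms, drop = FALSE]) *
        config$prm_effect_size
    } else rep(0, n)
    env_signal <- config$saponin_env_effect * truth$env_factors[, 1]
    nm <- saponin_names(config$n_saponins)
    out <- tibble(sample_id = sim$abundance$sample_id)
    for (s in seq_len(config$n_saponins)) {
      alpha <- rnorm(1, 0, 0.3)
      noise <- rnorm(n, 0, config$noise_sd)
      out[[nm[s]]] <- exp(alpha + prm_signal + env_signal + noise)
    }
    out
  })
}
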