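# order -> (class, phylum) lookup for the synthetic taxonomy; real fungal
# lineages so downstream summaries read naturally
fungal_order_lineages <- function() {
  tibble::tribble(
    ~order,            ~class,              ~phylum,
    "Pleosporales",    "Dothideomycetes",   "Ascomycota",
    "Capnodiales",     "Dothideomycetes",   "Ascomycota",
    "Chaetothyriales", "Eurotiomycetes",    "Ascomycota",
    "Eurotiales",      "Eurotiomycetes",    "Ascomycota",
    "Helotiales",      "Leotiomycetes",     "Ascomycota",
    "Hypocreales",     "Sordariomycetes",   "Ascomycota",
    "Xylariales",      "Sordariomycetes",   "Ascomycota",
    "Agaricales",      "Agaricomycetes",    "Basidiomycota"
  )
}

#' Simulate a 7-rank taxonomy and functional-guild table
#'
#' Draws for each ASV a kingdom..species lineage from a pool of real fungal
#' orders (with construction-consistent class/phylum prefixes and two
#' synthetic families x two genera per order; Pleosporales additionally
#' carries *Epicoccum* and *Coniothyrium*) and a functional guild label with
#' a confidence tag, emulating the inputs a guild-annotation tool would
#' provide.
#'
#' @param n_asvs Number of ASVs.
#' @param orders Character vector of fungal orders to draw from; must be a
#'   subset of the built-in pool.
#' @param guild_probs Named numeric vector of guild probabilities over
#'   `plant_pathogen`, `endophyte`, `epiphyte`, `saprotroph`, `unassigned`;
#'   must sum to 1.
#' @param seed Integer seed.
#' @return A list with `taxonomy` (tibble: `asv_id`, kingdom..species) and
#'   `guilds` (tibble: `asv_id`, `guild`, `confidence`).
#' @export
#' @examples
#' tg <- simulate_taxonomy_guilds(10, seed = 1)
#' tg$taxonomy
simulate_taxonomy_guilds <- function(n_asvs,
                                     orders = fungal_order_lineages()$order,
                                     guild_probs = c(plant_pathogen = 0.2,
                                                     endophyte = 0.3,
                                                     epiphyte = 0.2,
                                                     saprotroph = 0.2,
                                                     unassigned = 0.1),
                                     seed = 1L) {
  if (length(orders) == 0) abort("orders must be a non-empty character vector")
  pool <- fungal_order_lineages()
  if (!all(orders %in% pool$order)) abort("unknown fungal order requested")
  if (abs(sum(guild_probs) - 1) > 1e-8) abort("guild_probs must sum to 1")
  withr::with_seed(seed, {
    asv_ids <- sprintf("ASV_%03d", seq_len(n_asvs))
    pool <- pool[pool$order %in% orders, , drop = FALSE]

    # two families x two genera per order, plus the Pleosporales genera the
    # cross-species summaries care about
    fam_of_genus <- list()
    ord_of_fam <- list()
    for (o in pool$order) {
      for (fi in 1:2) {
        fam <- paste0(substr(o, 1, nchar(o) - 4), "aceae_", fi)
        ord_of_fam[[fam]] <- o
        for (gi in 1:2) {
          fam_of_genus[[paste0("Genus_", substr(o, 1, 4), "_", fi, gi)]] <- fam
        }
      }
    }
    if ("Pleosporales" %in% pool$order) {
      ord_of_fam[["Didymellaceae"]] <- "Pleosporales"
      ord_of_fam[["Coniothyriaceae"]] <- "Pleosporales"
      fam_of_genus[["Epicoccum"]] <- "Didymellaceae"
      fam_of_genus[["Coniothyrium"]] <- "Coniothyriaceae"
    }
    genera <- names(fam_of_genus)
    g <- sample(genera, n_asvs, replace = TRUE)
    fam <- unlist(fam_of_genus)[g]
    ord <- unlist(ord_of_fam)[fam]
    cls <- pool$class[match(ord, pool$order)]
    phy <- pool$phylum[match(ord, pool$order)]

    taxonomy <- tibble(
      asv_id = asv_ids, kingdom = "Fungi", phylum = phy, class = cls,
      order = unname(ord), family = unname(fam), genus = unname(g),
      species = paste0(unname(g), "_sp")
    )

    guild <- sample(names(guild_probs), n_asvs, replace = TRUE, prob = guild_probs)
    confidence <- sample(c("Highly Probable", "Probable", "Possible"),
                         n_asvs, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    confidence[guild == "unassigned"] <- NA_character_
    guilds <- tibble(asv_id = asv_ids, guild = guild, confidence = confidence)

    list(taxonomy = taxonomy, guilds = guilds)
  })
}

#' Write a simulated data set to a directory of TSV files
#'
#' Emits `abundance.tsv`, `env.tsv`, `coords.tsv`, `saponins.tsv`,
#' `taxonomy.tsv`, `guilds.tsv` and `truth.json` so downstream stages can be
#' replayed from files alone.
#'
#' @param sim Output of [simulate_community()].
#' @param saponins Output of [simulate_saponins()].
#' @param taxonomy_guilds Output of [simulate_taxonomy_guilds()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, saponins, taxonomy_guilds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wr(sim$abundance, "abundance.tsv")
  wr(sim$env, "env.tsv")
  wr(sim$coords, "coords.tsv")
  wr(saponins, "saponins.tsv")
  wr(taxonomy_guilds$taxonomy, "taxonomy.tsv")
  wr(taxonomy_guilds$guilds, "guilds.tsv")
  truth <- sim$truth
  jsonlite::write_json(
    list(
      module_of_asv = as.list(truth$module_of_asv),
      planted_prms = truth$planted_prms,
      planted_env_links = truth$planted_env_links,
      planted_dispersal_links = truth$planted_dispersal_links,
      dispersal_asvs = truth$dispersal_asvs,
      path_coefficients = truth$path_coefficients
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}

#' Read an abundance table written by [write_simulation()]
#'
#' @param path Path to a tab-delimited samples x ASVs count table whose
#'   first column is `sample_id`.
#' @return A tibble.
#' @export
read_abundance <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       check.names = FALSE, stringsAsFactors = FALSE))
}
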