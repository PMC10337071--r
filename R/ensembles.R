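#' Compare an observed metric against an Erdős–Rényi ensemble
#'
#' Samples `n_rep` G(n, m) graphs with the observed node and edge counts,
#' evaluates `metric` on each, and flags the observed value as significant
#' when it deviates from the ensemble mean by more than 1.96 standard
#' deviations (two-sided normal criterion).
#'
#' @param n,m Node and edge counts of the observed graph.
#' @param metric Function taking an igraph and returning a numeric scalar.
#' @param observed Observed value of the metric.
#' @param n_rep Ensemble size (default 100).
#' @param seed Integer seed.
#' @param name Metric label carried into the output.
#' @return One-row tibble: `metric`, `observed`, `mean`, `sd`, `z`,
#'   `n_rep`, `significant`.
#' @export
er_ensemble <- function(n, m, metric, observed, n_rep = 100, seed = 1L,
                        name = deparse(substitute(metric))) {
  if (m > n * (n - 1) / 2) abort("more edges requested than the graph can hold")
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      metric(igraph::sample_gnm(n, m))
    }, numeric(1))
  })
  mu <- mean(vals)
  s <- sd(vals)
  z <- if (s > 0) (observed - mu) / s else ifelse(observed == mu, 0, Inf)
  tibble(metric = name, observed = observed, mean = mu, sd = s, z = z,
         n_rep = as.integer(n_rep), significant = abs(observed - mu) > 1.96 * s)
}

#' Full ensemble comparison panel for an observed network
#'
#' Runs [er_ensemble()] for the complexity and efficiency panel (clustering
#' coefficient, degree centralization, fast-greedy modularity, natural
#' connectivity, global efficiency, average path length) with
#' per-metric seeds derived from `seed`.
#'
#' @param net A `phyllonet_men` or igraph.
#' @param n_rep Ensemble size (default 100).
#' @param seed Master seed.
#' @return Tibble with one row per metric.
#' @export
ensemble_panel <- function(net, n_rep = 100, seed = 1L) {
  g <- as_unweighted_graph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  metrics <- list(
    clustering_coefficient = function(x)
      igraph::transitivity(x, type = "localaverage", isolates = "zero"),
    degree_centralization = function(x) {
      k <- igraph::degree(x)
      sum(max(k) - k) / ((igraph::vcount(x) - 1) * (igraph::vcount(x) - 2))
    },
    modularity = function(x)
      igraph::modularity(igraph::cluster_fast_greedy(igraph::simplify(x))),
    natural_connectivity = natural_connectivity,
    global_efficiency = global_efficiency,
    avg_l = avg_path_length
  )
  obs <- complexity_indices(net)
  dplyr::bind_rows(purrr::imap(metrics, function(f, nm) {
    er_ensemble(n, m, f, observed = obs[[nm]], n_rep = n_rep,
                seed = derive_seed(seed, paste0("er_", nm)), name = nm)
  }))
}

#' Natural connectivity under random node removal
#'
#' For each removal fraction, removes that share of nodes uniformly at
#' random `n_rep` times and records the natural connectivity of the induced
#' subgraph -- the robustness curve of the network.
#'
#' @param net A `phyllonet_men` or igraph.
#' @param fractions Removal fractions in (0, 1) (default 0.2, 0.3, 0.4).
#' @param n_rep Replicates per fraction (default 100).
#' @param seed Integer seed.
#' @return Tibble of class `phyllonet_removal`: `fraction`, `mean`, `sd`,
#'   `n_rep`.
#' @export
robustness_removal <- function(net, fractions = c(0.2, 0.3, 0.4),
                               n_rep = 100, seed = 1L) {
  g <- as_unweighted_graph(net)
  n <- igraph::vcount(g)
  if (any(fractions <= 0 | fractions >= 1)) abort("fractions must lie in (0, 1)")
  if (any(floor(fractions * n) >= n)) abort("a fraction would remove every node")
  out <- withr::with_seed(seed, {
    purrr::map(fractions, function(f) {
      k <- floor(f * n)
      vals <- vapply(seq_len(n_rep), function(i) {
        keep <- sample.int(n, n - k)
        natural_connectivity(igraph::induced_subgraph(g, keep))
      }, numeric(1))
      tibble(fraction = f, mean = mean(vals), sd = sd(vals),
             n_rep = as.integer(n_rep))
    })
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("phyllonet_removal", class(out))
  out
}

#' @describeIn robustness_removal Robustness curve (mean +/- sd natural
#'   connectivity vs removal fraction).
#' @param object A `phyllonet_removal` tibble.
#' @param ... Unused.
#' @export
autoplot.phyllonet_removal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of nodes removed",
                  y = "remaining natural connectivity") +
    ggplot2::theme_minimal()
}
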