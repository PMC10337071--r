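#' Within-module degree z-score and participation coefficient
#'
#' For each node, `z` standardises its within-module degree against the
#' other members of its module, and `p` measures how evenly its links
#' spread across modules (`1 - sum((k_is / k_i)^2)`).  Roles follow the
#' (2.5, 0.62) cuts: kinless hub (`z > 2.5`, `p > 0.62`), provincial hub
#' (`z > 2.5`, `p <= 0.62`), connector (`z <= 2.5`, `p > 0.62`), peripheral
#' otherwise.  Modules with zero degree spread give `z = 0`.
#'
#' @param net A `phyllonet_men` or igraph.
#' @param partition A [detect_modules()] partition covering every node.
#' @return Tibble of class `phyllonet_roles`: `node`, `module`, `z`, `p`,
#'   `role`.
#' @export
zi_pi <- function(net, partition) {
  g <- as_unweighted_graph(net)
  nodes <- igraph::V(g)$name
  memb <- partition$membership$module[match(nodes, partition$membership$node)]
  if (any(is.na(memb))) abort("every node must be assigned a module")
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) != 0
  mods <- sort(unique(memb))
  # k_is: links of node i into module s
  k_is <- vapply(mods, function(s) rowSums(a[, memb == s, drop = FALSE]),
                 numeric(length(nodes)))
  if (length(nodes) == 1) k_is <- matrix(k_is, nrow = 1)
  k <- rowSums(k_is)
  within <- k_is[cbind(seq_along(nodes), match(memb, mods))]
  z <- vapply(seq_along(nodes), function(i) {
    grp <- within[memb == memb[i]]
    s <- sd(grp)
    if (is.na(s) || s == 0) 0 else (within[i] - mean(grp)) / s
  }, numeric(1))
  p <- unname(1 - rowSums((k_is / pmax(k, 1))^2))
  p[k == 0] <- 0
  role <- dplyr::case_when(
    z > 2.5 & p > 0.62 ~ "kinless hub",
    z > 2.5 ~ "provincial hub",
    p > 0.62 ~ "connector",
    TRUE ~ "peripheral"
  )
  out <- tibble(node = nodes, module = memb, z = z, p = p, role = role)
  class(out) <- c("phyllonet_roles", class(out))
  out
}

#' @describeIn zi_pi z-P scatter with the (2.5, 0.62) role cuts.
#' @param object A `phyllonet_roles` tibble.
#' @param ... Unused.
#' @export
autoplot.phyllonet_roles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$p, .data$z, colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 2.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.62, linetype = 2) +
    ggplot2::labs(x = "participation coefficient (P)",
                  y = "within-module degree (z)", colour = NULL) +
    ggplot2::theme_minimal()
}

# generalised (Hurwitz) zeta sum_{k=xmin}^Inf k^-alpha, by direct summation
# with an integral tail correction
hurwitz_zeta <- function(alpha, xmin, n_terms = 1e4) {
  k <- seq(xmin, xmin + n_terms - 1)
  sum(k^(-alpha)) + (xmin + n_terms - 0.5)^(1 - alpha) / (alpha - 1)
}

# discrete power-law MLE for fixed xmin
powerlaw_mle <- function(x, xmin) {
  nll <- function(alpha) {
    alpha * sum(log(x)) + length(x) * log(hurwitz_zeta(alpha, xmin))
  }
  stats::optimize(nll, c(1.01, 8))$minimum
}

powerlaw_ks_stat <- function(x, xmin, alpha, kmax) {
  k <- xmin:kmax
  pmf <- k^(-alpha)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  emp <- vapply(k, function(v) mean(x <= v), numeric(1))
  max(abs(emp - cdf))
}

#' Power-law fit to the upper degree tail
#'
#' Fits a discrete power law by maximum likelihood to node degrees at or
#' above the median degree (`x_min` fixed at the median) and tests
#' goodness of fit with a parametric-bootstrap Kolmogorov-Smirnov test:
#' degree samples are redrawn from the fitted law, refitted, and the
#' p-value is the fraction of bootstrap KS statistics at least as large as
#' the observed one.  Following the scale-free taxonomy used for these
#' networks, a passing fit (`p > 0.05`) covering more than 50 nodes is
#' classed `"weak"` scale-free, a passing fit covering fewer is
#' `"weakest"`, and a rejected fit is `"not"` scale-free.
#'
#' @param net A `phyllonet_men`, igraph, or a raw integer degree vector
#'   (at least 10 nodes).
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `x_min` (median degree), `exponent`,
#'   `ks_pvalue`, `n_covered`, `sf_class`.
#' @export
tail_powerlaw <- function(net, n_boot = 200, seed = 1L) {
  deg <- if (is.numeric(net)) net else igraph::degree(as_unweighted_graph(net))
  if (length(deg) < 10) abort("need at least 10 nodes for a tail fit")
  x_min <- max(1, floor(median(deg)))
  tail_deg <- deg[deg >= x_min]
  n_cov <- length(tail_deg)
  if (length(unique(tail_deg)) < 2) {
    return(tibble(x_min = x_min, exponent = NA_real_, ks_pvalue = NaN,
                  n_covered = n_cov, sf_class = "not"))
  }
  alpha <- powerlaw_mle(tail_deg, x_min)
  kmax <- max(1000L, 10L * max(tail_deg))
  d_obs <- powerlaw_ks_stat(tail_deg, x_min, alpha, kmax)
  k <- x_min:kmax
  pmf <- k^(-alpha)
  d_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- sample(k, n_cov, replace = TRUE, prob = pmf)
      ab <- powerlaw_mle(xb, x_min)
      powerlaw_ks_stat(xb, x_min, ab, kmax)
    }, numeric(1))
  })
  ks_p <- mean(d_boot >= d_obs)
  sf <- if (is.na(ks_p) || ks_p <= 0.05) "not"
  else if (n_cov > 50) "weak"
  else "weakest"
  tibble(x_min = x_min, exponent = alpha, ks_pvalue = ks_p,
         n_covered = n_cov, sf_class = sf)
}
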