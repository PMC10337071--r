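#' Drop rare ASVs by overall relative abundance
#'
#' Retains ASVs whose overall relative abundance (column total over the
#' grand total) is strictly greater than `min_rel_abund`, the usual guard
#' against spurious correlations driven by rare taxa.
#'
#' @param abund Abundance tibble (`sample_id` + count columns).
#' @param min_rel_abund Relative-abundance cutoff (default 1e-4, i.e.
#'   0.01%).
#' @return The filtered abundance tibble, column order preserved.
#' @export
abundance_filter <- function(abund, min_rel_abund = 1e-4) {
  m <- abund_matrix(abund)
  if (any(rowSums(m) <= 0)) abort("abundance table has empty samples")
  rel <- colSums(m) / sum(m)
  keep <- rel > min_rel_abund
  if (!any(keep)) abort("all ASVs removed by the relative-abundance filter")
  dplyr::select(abund, "sample_id", dplyr::all_of(names(which(keep))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone-enforced and capped at
#' 1, in the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (same length and order).
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Pairwise Spearman correlation matrix with BH-masked significance
#'
#' Computes all pairwise Spearman correlations (mid-rank ties), two-sided
#' p-values from the t approximation on `n - 2` degrees of freedom, and BH
#' q-values adjusted over the strict upper triangle only.  Zero-variance
#' ASVs get rho = 0 and q = 1 (with a warning) rather than propagating NaN.
#'
#' @param abund Abundance tibble (`sample_id` + numeric columns).
#' @return A list of class `phyllonet_cor` with symmetric matrices `rho`,
#'   `pval`, `qval`, the sample size `n`, and `asv_ids`.
#' @export
spearman_matrix <- function(abund) {
  m <- abund_matrix(abund)
  n <- nrow(m)
  p <- ncol(m)
  if (n < 4) abort("need at least 4 samples for correlation analysis")
  if (p < 2) abort("need at least 2 ASVs")
  degenerate <- apply(m, 2, function(x) var(x) == 0)
  if (any(degenerate)) {
    warn(paste0(sum(degenerate), " zero-variance ASV(s): rho set to 0, q to 1"))
  }
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[degenerate, ] <- 0
  rho[, degenerate] <- 0
  diag(rho) <- 1

  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1] <- 0
  diag(pval) <- 0
  pval[degenerate, ] <- 1
  pval[, degenerate] <- 1
  diag(pval) <- 0

  up <- upper.tri(pval)
  qval <- pval
  qval[up] <- bh_adjust(pval[up])
  qval[lower.tri(qval)] <- t(qval)[lower.tri(qval)]
  diag(qval) <- 0
  qval[degenerate, ] <- 1
  qval[, degenerate] <- 1
  diag(qval) <- 0

  structure(
    list(rho = rho, pval = pval, qval = qval, n = n, asv_ids = colnames(m)),
    class = "phyllonet_cor"
  )
}

#' @export
print.phyllonet_cor <- function(x, ...) {
  cat("Spearman correlation matrix:", length(x$asv_ids), "ASVs,",
      x$n, "samples\n")
  invisible(x)
}

#' @describeIn spearman_matrix One row per unordered ASV pair with `rho`,
#'   `pval` and `qval`.
#' @param x A `phyllonet_cor` object.
#' @param ... Unused.
#' @export
tidy.phyllonet_cor <- function(x, ...) {
  up <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    asv_i = x$asv_ids[up[, 1]], asv_j = x$asv_ids[up[, 2]],
    rho = x$rho[up], pval = x$pval[up], qval = x$qval[up]
  )
}

# first-order partial correlation of ranked x, y given ranked z
partial_spearman <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (!is.finite(den) || den < .Machine$double.eps) return(0)
  (rxy - rxz * ryz) / den
}
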