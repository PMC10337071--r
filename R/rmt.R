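# Unfold a spectrum and score its nearest-neighbour spacing distribution
# (NNSD) against the Poisson law exp(-s) and the GOE Wigner surmise
# (pi*s/2)*exp(-pi*s^2/4).  Lower chi-square = better fit.
#
# Unfolding: dedupe eigenvalues (tolerance 1e-8; thresholded correlation
# matrices carry high-multiplicity eigenvalues from isolated nodes), fit a
# cubic smoothing spline to the empirical cumulative spectral density, map
# eigenvalues through it, and take successive differences normalised to
# unit mean.
nnsd_fit <- function(eigenvalues, nbins = 40, spline_df = 10) {
  lam <- sort(eigenvalues)
  lam <- lam[c(TRUE, diff(lam) > 1e-8)]
  k <- length(lam)
  if (k < 12) {
    return(list(n_spacings = max(k - 1L, 0L), poisson_stat = NA_real_,
                goe_stat = NA_real_, poisson_p = NA_real_, usable = FALSE))
  }
  fit <- smooth.spline(lam, seq_len(k) / k, df = min(spline_df, k - 2))
  unfolded <- k * predict(fit, lam)$y
  s <- diff(unfolded)
  s <- s[s > 0]
  if (length(s) < 10) {
    return(list(n_spacings = length(s), poisson_stat = NA_real_,
                goe_stat = NA_real_, poisson_p = NA_real_, usable = FALSE))
  }
  s <- s / mean(s)

  breaks <- seq(0, max(s), length.out = nbins + 1)
  breaks[length(breaks)] <- Inf
  obs <- tabulate(findInterval(s, breaks, rightmost.closed = TRUE),
                  nbins = nbins)
  n <- length(s)
  cdf_pois <- function(x) 1 - exp(-x)
  cdf_goe <- function(x) 1 - exp(-pi * x^2 / 4)
  chisq_vs <- function(cdf) {
    expd <- n * diff(c(cdf(breaks[-length(breaks)]), 1))
    sum((obs - expd)^2 / pmax(expd, 1e-12))
  }
  pois <- chisq_vs(cdf_pois)
  goe <- chisq_vs(cdf_goe)
  list(
    n_spacings = n, poisson_stat = pois, goe_stat = goe,
    poisson_p = pchisq(pois, df = nbins - 2, lower.tail = FALSE),
    usable = TRUE
  )
}

#' Scan correlation thresholds for the RMT Poisson/GOE transition
#'
#' For each candidate cutoff `t` the BH-masked correlation matrix (entries
#' with q > `fdr` zeroed) is additionally thresholded at `|rho| >= t`,
#' eigen-decomposed, its spectrum unfolded with a cubic smoothing spline,
#' and the nearest-neighbour spacing distribution scored against the
#' Poisson law (uncorrelated system) and the GOE Wigner surmise (random
#' matrix).  The transition from GOE-like to Poisson-like spacings marks
#' the cutoff at which random noise has been removed and only
#' system-specific structure remains.
#'
#' @param corr A [spearman_matrix()] object.
#' @param t_min,t_max,step Candidate threshold grid (strictly increasing
#'   within \[0, 1)).
#' @param fdr q-value mask applied before scanning (default 0.05).
#' @param nbins Histogram bins for the spacing goodness-of-fit (default 40).
#' @param spline_df Degrees of freedom of the unfolding spline (default 10).
#' @return A tibble of class `phyllonet_rmt_scan` with one row per
#'   threshold: `threshold`, `n_spacings`, `poisson_stat`, `goe_stat`,
#'   `poisson_p`, `usable`.
#' @export
rmt_scan <- function(corr, t_min = 0.3, t_max = 0.99, step = 0.01,
                     fdr = 0.05, nbins = 40, spline_df = 10) {
  stopifnot(inherits(corr, "phyllonet_cor"))
  if (t_min < 0 || t_max >= 1 || t_min > t_max || step <= 0) {
    abort("threshold grid must be strictly increasing within [0, 1)")
  }
  masked <- corr$rho
  masked[corr$qval > fdr] <- 0
  diag(masked) <- 1
  grid <- seq(t_min, t_max, by = step)
  rows <- purrr::map(grid, function(t) {
    a <- masked
    a[abs(a) < t] <- 0
    diag(a) <- 1
    fit <- nnsd_fit(eigen(a, symmetric = TRUE, only.values = TRUE)$values,
                    nbins = nbins, spline_df = spline_df)
    tibble(threshold = t, n_spacings = fit$n_spacings,
           poisson_stat = fit$poisson_stat, goe_stat = fit$goe_stat,
           poisson_p = fit$poisson_p, usable = fit$usable)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phyllonet_rmt_scan", class(out))
  out
}

#' Select the RMT transition threshold from a scan
#'
#' Returns the smallest usable threshold at which the Poisson fit statistic
#' beats the GOE fit statistic and the Poisson chi-square goodness of fit is
#' not rejected at `alpha`.  Deterministic given the scan.
#'
#' @param scan A [rmt_scan()] result.
#' @param alpha Rejection level for the Poisson goodness-of-fit test.
#' @return The selected threshold (numeric scalar).
#' @export
select_transition <- function(scan, alpha = 0.05) {
  stopifnot(inherits(scan, "phyllonet_rmt_scan"))
  ok <- scan$usable & !is.na(scan$poisson_stat) &
    scan$poisson_stat < scan$goe_stat & scan$poisson_p >= alpha
  if (!any(ok)) {
    abort("no threshold shows a Poisson-favoured spacing distribution; widen the scan grid")
  }
  min(scan$threshold[ok])
}

#' @describeIn rmt_scan Plot Poisson and GOE fit statistics across the
#'   threshold grid, with the selected transition marked when available.
#' @param object A `phyllonet_rmt_scan` object.
#' @param ... Unused.
#' @export
autoplot.phyllonet_rmt_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("threshold", "poisson_stat", "goe_stat")],
    -"threshold", names_to = "law", values_to = "chisq"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$chisq,
                                          colour = .data$law)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(poisson_stat = "#1b9e77", goe_stat = "#d95f02"),
      labels = c(poisson_stat = "Poisson", goe_stat = "GOE (Wigner)")
    ) +
    ggplot2::labs(x = "correlation threshold",
                  y = expression(chi^2 ~ "of NNSD fit"), colour = NULL) +
    ggplot2::theme_minimal()
  tr <- tryCatch(select_transition(object), error = function(e) NULL)
  if (!is.null(tr)) p <- p + ggplot2::geom_vline(xintercept = tr, linetype = 2)
  p
}
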