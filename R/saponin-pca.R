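#' Summarise a saponin table by covariance PCA and total content
#'
#' PCA on the centred but unscaled saponin matrix (the contents are
#' absolute quantifications on a common mg/g scale, so no standardisation
#' is applied); PC1 summarises the saponin profile and the row sum gives
#' total saponin content.
#'
#' @param sap Saponin tibble (`sample_id` + one column per saponin, mg/g).
#' @return A list of class `phyllonet_saponin`: `pc1` (per-sample scores),
#'   `var_explained` (fraction of variance on PC1), `total` (per-sample
#'   total content), `loadings`, `var_fractions` (all components).
#' @export
saponin_pca <- function(sap) {
  m <- meta_matrix(sap)
  if (nrow(m) < 3) abort("need at least 3 samples for a PCA")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      pc1 = setNames(pc$x[, 1], rownames(m)),
      var_explained = fr[1],
      total = setNames(rowSums(m), rownames(m)),
      loadings = pc$rotation[, 1],
      var_fractions = fr
    ),
    class = "phyllonet_saponin"
  )
}

#' @export
print.phyllonet_saponin <- function(x, ...) {
  cat("Saponin summary:", length(x$pc1), "samples, PC1 explains",
      sprintf("%.1f%%", 100 * x$var_explained), "of variance\n")
  invisible(x)
}

#' Drop collinear environmental variables
#'
#' While any pair of variables has Spearman rho^2 above `rho2_cut`, removes
#' the member of the worst pair with the larger mean absolute correlation
#' to all remaining variables.
#'
#' @param env Environment tibble (`sample_id` + numeric variables).
#' @param rho2_cut Squared-correlation cutoff (default 0.6).
#' @return The filtered environment tibble.
#' @export
collinearity_filter <- function(env, rho2_cut = 0.6) {
  vars <- setdiff(names(env), "sample_id")
  if (length(vars) == 0) abort("no environmental variables supplied")
  repeat {
    if (length(vars) < 2) break
    r2 <- cor(as.matrix(env[vars]), method = "spearman")^2
    diag(r2) <- 0
    if (max(r2) <= rho2_cut) break
    worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(abs(sqrt(r2)))
    drop <- vars[worst[which.max(mean_abs[worst])]]
    vars <- setdiff(vars, drop)
  }
  dplyr::select(env, "sample_id", dplyr::all_of(vars))
}

#' Log-transform environmental variables for normality
#'
#' Applies `log` to every variable except soil pH (already on a log scale),
#' the conventional pre-treatment before correlation screening.
#'
#' @param env Environment tibble with positive-valued variables.
#' @param skip Variables left untransformed (default `"pH"`).
#' @return Transformed tibble.
#' @export
log_transform_env <- function(env, skip = "pH") {
  for (v in setdiff(names(env), c("sample_id", skip))) {
    if (any(env[[v]] <= 0)) {
      warn(paste0("non-positive values in ", v, ": left untransformed"))
    } else {
      env[[v]] <- log(env[[v]])
    }
  }
  env
}

#' Screen candidate modules and environmental factors against saponin PC1
#'
#' Spearman correlation of each module eigengene and each environmental
#' variable against the saponin PC1, with BH FDR applied within each family
#' (modules, environment) separately; candidates are FDR < `fdr`.
#'
#' @param eigengenes Eigengene scores tibble from [module_eigengenes()].
#' @param env Environment tibble (after [collinearity_filter()]).
#' @param sap A [saponin_pca()] summary.
#' @param fdr Candidate threshold (default 0.05).
#' @return Tibble: `variable`, `family` (`"module"` or `"environment"`),
#'   `rho`, `pval`, `fdr`, `candidate`.
#' @export
screen_candidates <- function(eigengenes, env, sap, fdr = 0.05) {
  check_sample_alignment(eigengenes, env)
  pc1 <- sap$pc1[as.character(eigengenes$sample_id)]
  screen_family <- function(tbl, family) {
    vars <- setdiff(names(tbl), "sample_id")
    rows <- purrr::map(vars, function(v) {
      ct <- suppressWarnings(
        stats::cor.test(tbl[[v]], pc1, method = "spearman", exact = FALSE))
      tibble(variable = v, family = family,
             rho = unname(ct$estimate), pval = ct$p.value)
    })
    out <- dplyr::bind_rows(rows)
    out$fdr <- bh_adjust(out$pval)
    out
  }
  out <- dplyr::bind_rows(
    screen_family(eigengenes, "module"),
    screen_family(env, "environment")
  )
  out$candidate <- out$fdr < fdr
  out
}
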