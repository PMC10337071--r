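#' Compare feature sets for predicting the saponin profile
#'
#' Fits random-forest and k-nearest-neighbour regressions of a response
#' (typically the saponin PC1) on each supplied feature set under one
#' shared k-fold assignment, so models are compared on identical
#' held-out samples.  Performance is the fold-averaged mean squared error
#' and the fold-averaged Spearman correlation between held-out truth and
#' prediction; lower MSE or higher rho indicates the better model.
#'
#' @param feature_sets Named list of feature tibbles/data frames (rows
#'   sample-aligned with `response`), e.g. `Env`, `EnvLE`, `EnvLP`,
#'   `EnvALL`.  Empty sets are skipped with a warning.
#' @param response Numeric response vector.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment and the
#'   random-forest fits.
#' @param knn_k Neighbours for the KNN learner (default 7).
#' @param rf_trees Trees for the random forest (default 500).
#' @return Tibble of class `phyllonet_ml`: `model`, `learner`, `mse`,
#'   `spearman_rho`, `k_folds`.
#' @export
ml_compare <- function(feature_sets, response, k_folds = 5, seed = 1L,
                       knn_k = 7, rf_trees = 500) {
  n <- length(response)
  if (n < k_folds) abort("need at least as many samples as folds")
  keep <- vapply(feature_sets, function(x) !is.null(x) && ncol(x) > 0, logical(1))
  if (!all(keep)) {
    warn(paste("empty feature set(s) skipped:",
               paste(names(feature_sets)[!keep], collapse = ", ")))
    feature_sets <- feature_sets[keep]
  }
  feature_sets <- purrr::map(feature_sets, function(x) {
    x <- as.data.frame(x)
    x[setdiff(names(x), "sample_id")]
  })

  out <- withr::with_seed(seed, {
    folds <- sample(rep(seq_len(k_folds), length.out = n))
    purrr::imap(feature_sets, function(feats, model_name) {
      purrr::map(c("RF", "KNN"), function(learner) {
        fold_scores <- purrr::map(seq_len(k_folds), function(f) {
          tr <- folds != f
          x_tr <- feats[tr, , drop = FALSE]
          x_te <- feats[!tr, , drop = FALSE]
          pred <- if (learner == "RF") {
            fit <- randomForest::randomForest(x = x_tr, y = response[tr],
                                              ntree = rf_trees)
            as.numeric(predict(fit, x_te))
          } else {
            fit <- caret::knnreg(x_tr, response[tr],
                                 k = min(knn_k, sum(tr)))
            as.numeric(predict(fit, x_te))
          }
          truth <- response[!tr]
          rho <- if (length(truth) > 2 && sd(pred) > 0) {
            suppressWarnings(cor(truth, pred, method = "spearman"))
          } else NA_real_
          c(mse = mean((truth - pred)^2), rho = rho)
        })
        sc <- do.call(rbind, fold_scores)
        tibble(model = model_name, learner = learner,
               mse = mean(sc[, "mse"]),
               spearman_rho = mean(sc[, "rho"], na.rm = TRUE),
               k_folds = as.integer(k_folds))
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(out))
  class(out) <- c("phyllonet_ml", class(out))
  out
}

#' Assemble the four standard feature sets for [ml_compare()]
#'
#' `Env` holds the candidate environmental factors alone; `EnvLE` and
#' `EnvLP` add the candidate module eigengenes of the leaf-endosphere and
#' phylloplane networks respectively; `EnvALL` adds both.
#'
#' @param env Environment tibble restricted to candidate factors.
#' @param eig_le,eig_lp Candidate eigengene tibbles for the two
#'   compartments (either may be `NULL`).
#' @return Named list of feature tibbles.
#' @export
ml_feature_sets <- function(env, eig_le = NULL, eig_lp = NULL) {
  drop_id <- function(x) if (is.null(x)) NULL else x[setdiff(names(x), "sample_id")]
  env_f <- drop_id(env)
  le <- drop_id(eig_le)
  lp <- drop_id(eig_lp)
  list(
    Env = env_f,
    EnvLE = if (!is.null(le)) dplyr::bind_cols(env_f, le) else NULL,
    EnvLP = if (!is.null(lp)) dplyr::bind_cols(env_f, lp) else NULL,
    EnvALL = dplyr::bind_cols(c(list(env_f), Filter(Negate(is.null), list(le, lp))))
  )
}

#' @describeIn ml_compare Grouped bar chart of MSE (or Spearman rho) per
#'   model and learner.
#' @param object A `phyllonet_ml` tibble.
#' @param metric `"mse"` or `"spearman_rho"`.
#' @param ... Unused.
#' @export
autoplot.phyllonet_ml <- function(object, metric = c("mse", "spearman_rho"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(.data$model, .data[[metric]],
                                       fill = .data$learner)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}
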