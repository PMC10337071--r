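# parse "y ~ x1 + x2" regression strings into (lhs, rhs) pairs
parse_path_model <- function(model) {
  purrr::map(model, function(eq) {
    parts <- strsplit(eq, "~", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste("malformed path equation:", eq))
    lhs <- trimws(parts[1])
    rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    list(lhs = lhs, rhs = rhs[nzchar(rhs)])
  })
}

# implied covariance of a recursive observed-variable path model:
# Sigma = (I-B)^{-1} Psi (I-B)^{-T}, exogenous block of Psi fixed at the
# sample covariance, endogenous Psi diagonal (residual variances)
sem_implied <- function(theta, info) {
  p <- length(info$vars)
  b <- matrix(0, p, p, dimnames = list(info$vars, info$vars))
  for (i in seq_len(nrow(info$paths))) {
    b[info$paths$lhs[i], info$paths$rhs[i]] <- theta[i]
  }
  psi <- matrix(0, p, p, dimnames = list(info$vars, info$vars))
  psi[info$exog, info$exog] <- info$s_exog
  diag(psi)[info$endog] <- theta[nrow(info$paths) + seq_along(info$endog)]
  imb <- solve(diag(p) - b)
  imb %*% psi %*% t(imb)
}

# ML discrepancy F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p
sem_objective <- function(theta, info) {
  sigma <- sem_implied(theta, info)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) return(1e10)
  as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
    sum(diag(info$s %*% solve(sigma))) - info$logdet_s - length(info$vars)
}

sem_build_info <- function(data, model) {
  spec <- parse_path_model(model)
  vars <- unique(unlist(purrr::map(spec, function(s) c(s$lhs, s$rhs))))
  missing <- setdiff(vars, names(data))
  if (length(missing)) abort(paste("variables absent from data:",
                                   paste(missing, collapse = ", ")))
  paths <- dplyr::bind_rows(purrr::map(spec, function(s) {
    tibble(lhs = s$lhs, rhs = s$rhs)
  }))
  endog <- unique(paths$lhs)
  exog <- setdiff(vars, endog)
  x <- scale(as.matrix(data[vars]))          # standardised inputs
  s <- cov(x)
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    abort(paste0("sample covariance is not positive definite (min eigenvalue ",
                 format(min(ev), digits = 3),
                 "); check for collinear variables"))
  }
  list(vars = vars, paths = paths, endog = endog, exog = exog,
       s = s, s_exog = s[exog, exog, drop = FALSE],
       logdet_s = as.numeric(determinant(s, logarithm = TRUE)$modulus),
       n = nrow(x))
}

#' Fit an observed-variable path model by maximum likelihood
#'
#' Fits a recursive structural equation model over observed variables
#' (no latent constructs) by minimising the maximum-likelihood covariance
#' discrepancy `F = ln|Sigma(theta)| + tr(S Sigma(theta)^-1) - ln|S| - p`.
#' Inputs are z-standardised first, so path estimates are standardised
#' effects.  Fit statistics: `chi2 = (n - 1) F_min` with its test p-value,
#' the comparative fit index (CFI) against the independence baseline, and
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`.  A saturated model
#' (every covariance reproduced) gives `chi2 = 0` and `CFI = 1`.
#'
#' @param data Data frame of observed per-sample variables (environmental
#'   factors, module eigengenes, total saponin).
#' @param model Character vector of regression equations, e.g.
#'   `c("module ~ env", "saponin ~ env + module")`.
#' @return An object of class `phyllonet_sem` with `paths` (tibble `lhs`,
#'   `rhs`, `estimate`, `std_error`, `p_value`), `chi2`, `df`, `chi2_p`,
#'   `cfi`, `rmsea`, `n`, `converged`.
#' @export
fit_path_model <- function(data, model) {
  info <- sem_build_info(data, model)
  n_path <- nrow(info$paths)
  n_endog <- length(info$endog)

  # equation-by-equation OLS gives the ML solution of a recursive model and
  # serves as the optimiser start
  x <- scale(as.matrix(data[info$vars]))
  start <- numeric(n_path + n_endog)
  for (y in info$endog) {
    rhs <- info$paths$rhs[info$paths$lhs == y]
    fit <- stats::lm.fit(cbind(1, x[, rhs, drop = FALSE]), x[, y])
    start[which(info$paths$lhs == y)] <- fit$coefficients[-1]
    start[n_path + match(y, info$endog)] <-
      max(sum(fit$residuals^2) / (info$n - 1), 1e-6)
  }
  opt <- nlminb(start, sem_objective, info = info,
                lower = c(rep(-Inf, n_path), rep(1e-8, n_endog)))
  theta <- opt$par
  f_min <- max(opt$objective, 0)

  n <- info$n
  p <- length(info$vars)
  q <- length(info$exog)
  n_free <- n_path + n_endog + q * (q + 1) / 2
  df <- p * (p + 1) / 2 - n_free
  chi2 <- max((n - 1) * f_min, 0)
  if (df <= 0) chi2 <- 0

  # baseline independence model for CFI
  f_base <- sum(log(diag(info$s))) -
    info$logdet_s
  chi2_base <- (n - 1) * f_base
  df_base <- p * (p - 1) / 2
  num <- max(chi2 - df, 0)
  den <- max(chi2_base - df_base, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * (n - 1))) else 0

  # standard errors from the numerical Hessian of the discrepancy
  h <- tryCatch(stats::optimHess(theta, sem_objective, info = info),
                error = function(e) NULL)
  se <- rep(NA_real_, n_path)
  if (!is.null(h)) {
    cv <- tryCatch(2 / (n - 1) * solve(h), error = function(e) NULL)
    if (!is.null(cv)) {
      d <- diag(cv)[seq_len(n_path)]
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  est <- theta[seq_len(n_path)]
  paths <- dplyr::mutate(info$paths, estimate = est, std_error = se,
                         p_value = 2 * pnorm(-abs(est / se)))

  structure(
    list(paths = paths, chi2 = chi2, df = df,
         chi2_p = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
         cfi = cfi, rmsea = rmsea, n = n,
         converged = opt$convergence == 0),
    class = "phyllonet_sem"
  )
}

#' @export
print.phyllonet_sem <- function(x, ...) {
  cat(sprintf("Path model: chi2 = %.3f (df = %d%s), CFI = %.3f, RMSEA = %.3f\n",
              x$chi2, x$df,
              if (!is.na(x$chi2_p)) sprintf(", p = %.3f", x$chi2_p) else "",
              x$cfi, x$rmsea))
  print(x$paths)
  invisible(x)
}

#' @describeIn fit_path_model Standardised path estimates.
#' @param x A `phyllonet_sem` object.
#' @param ... Unused.
#' @export
tidy.phyllonet_sem <- function(x, ...) x$paths

#' @describeIn fit_path_model One-row fit summary (chi2, df, p, CFI,
#'   RMSEA, n).
#' @export
glance.phyllonet_sem <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, chi2_p = x$chi2_p, cfi = x$cfi,
         rmsea = x$rmsea, n = x$n, converged = x$converged)
}

#' Simulate data from the standard prior path model
#'
#' Draws standardised data from the chain environment -> module -> total
#' saponin, with configurable standardised path coefficients (the
#' environment -> saponin path defaults to zero), for parameter-recovery
#' checks of [fit_path_model()].
#'
#' @param n Sample size.
#' @param b_env_mod Standardised effect of environment on the module
#'   eigengene.
#' @param b_mod_sap Standardised effect of the module on total saponin.
#' @param b_env_sap Direct standardised effect of environment on saponin.
#' @param seed Integer seed.
#' @return Tibble with columns `env`, `module`, `saponin` (unit variance in
#'   expectation).
#' @export
simulate_path_data <- function(n, b_env_mod = 0.6, b_mod_sap = 0.585,
                               b_env_sap = 0, seed = 1L) {
  withr::with_seed(seed, {
    env <- rnorm(n)
    module <- b_env_mod * env + sqrt(max(1 - b_env_mod^2, 0.05)) * rnorm(n)
    resid_var <- 1 - (b_mod_sap^2 + b_env_sap^2 +
                        2 * b_mod_sap * b_env_sap * b_env_mod)
    saponin <- b_mod_sap * module + b_env_sap * env +
      sqrt(max(resid_var, 0.05)) * rnorm(n)
    tibble(env = env, module = module, saponin = saponin)
  })
}
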