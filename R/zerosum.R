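#' Log-ratio feature matrix from genus counts
#'
#' Computes `log((count + pseudocount) / (row total + G * pseudocount))`
#' per genus. Under the zero-sum coefficient constraint the linear
#' predictor depends only on log-ratios between features, so fitted values
#' are invariant to per-sample sequencing depth.
#'
#' @param t a genus-level [count_table()] or count matrix, one row per
#'   patient (early post-intervention samples).
#' @param pseudocount additive pseudocount (default 0.5).
#' @return Numeric matrix of log proportions.
#' @export
logratio_features <- function(t, pseudocount = 0.5) {
  X <- if (inherits(t, "count_table")) t$counts else as.matrix(t)
  if (ncol(X) < 2)
    stopf("zero-sum log-ratio model needs at least two features")
  log((X + pseudocount) / (rowSums(X) + ncol(X) * pseudocount))
}

#' Zero-sum constrained logistic lasso
#'
#' Minimizes the mean binomial deviance plus an L1 penalty subject to the
#' coefficients of the penalized (log-abundance) features summing to zero,
#' which makes the model a log-ratio model that is invariant to per-sample
#' scaling. Solved by an augmented Lagrangian outer loop (multiplier update
#' and penalty escalation until the constraint residual falls below 1e-6)
#' with IRLS plus cyclic coordinate descent inside.
#'
#' @param X numeric matrix of penalized features (log proportions from
#'   [logratio_features()]); no constant columns.
#' @param y binary outcome vector (0/1).
#' @param lambda nonnegative L1 penalty (scalar, or descending vector for a
#'   warm-started path).
#' @param covariates optional matrix of unpenalized, unconstrained
#'   covariates (e.g. PTCy-based prophylaxis indicator).
#' @param control list of solver settings: `tol`, `max_irls`, `max_outer`,
#'   `constraint_tol`.
#' @return For scalar `lambda`, an object of class `zerosum_fit` with
#'   elements `beta` (named), `intercept`, `covariate_coef`, `lambda`,
#'   `deviance`, `constraint_residual`, `converged`. For a vector, a
#'   `zerosum_path` list with matrices over the path.
#' @export
fit_zero_sum <- function(X, y, lambda, covariates = NULL,
                         control = list()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("y must be binary 0/1")
  if (length(y) != nrow(X)) stopf("length(y) != nrow(X)")
  if (any(apply(X, 2, function(v) max(v) - min(v)) == 0))
    stopf("constant penalized column(s) present")
  if (any(lambda < 0)) stopf("lambda must be >= 0")
  C <- if (is.null(covariates)) matrix(0, nrow(X), 0) else as.matrix(covariates)
  ctrl <- modifyList(list(tol = 1e-6, max_irls = 20, max_outer = 8,
                          constraint_tol = 1e-6), control)
  ord <- order(lambda, decreasing = TRUE)
  res <- zs_lasso_path_cpp(X, y, C, lambda[ord], tol = ctrl$tol,
                           max_irls = ctrl$max_irls, max_outer = ctrl$max_outer,
                           constraint_tol = ctrl$constraint_tol)
  inv <- order(ord)
  path <- list(beta = res$beta[, inv, drop = FALSE],
               intercept = res$intercept[inv],
               covariate_coef = if (ncol(C)) res$theta[, inv, drop = FALSE] else NULL,
               lambda = lambda, deviance = res$deviance[inv],
               constraint_residual = res$constraint_residual[inv],
               converged = res$converged[inv])
  rownames(path$beta) <- colnames(X)
  if (length(lambda) == 1) {
    structure(list(beta = setNames(path$beta[, 1], colnames(X)),
                   intercept = path$intercept[1],
                   covariate_coef = if (ncol(C)) path$covariate_coef[, 1] else NULL,
                   lambda = lambda, deviance = path$deviance[1],
                   constraint_residual = path$constraint_residual[1],
                   converged = path$converged[1]),
              class = "zerosum_fit")
  } else {
    structure(path, class = "zerosum_path")
  }
}

#' @export
print.zerosum_fit <- function(x, ...) {
  nz <- sum(abs(x$beta) > 1e-8)
  cat(sprintf("zero-sum logistic lasso: lambda = %.4g, %d/%d nonzero, deviance = %.3f\n",
              x$lambda, nz, length(x$beta), x$deviance))
  cat(sprintf("  constraint |sum(beta)| = %.2e%s\n", x$constraint_residual,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.zerosum_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta,
    if (!is.null(object$covariate_coef))
      setNames(object$covariate_coef,
               paste0("covariate", seq_along(object$covariate_coef))))
}

#' @export
predict.zerosum_fit <- function(object, newx, covariates = NULL,
                                type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- drop(as.matrix(newx) %*% object$beta) + object$intercept
  if (!is.null(object$covariate_coef)) {
    if (is.null(covariates)) stopf("fit has covariates; supply them")
    eta <- eta + drop(as.matrix(covariates) %*% object$covariate_coef)
  }
  if (type == "response") plogis(eta) else eta
}

# Smallest lambda at which all penalized coefficients are zero. At beta = 0
# the KKT conditions read |g_j + mu| <= lambda for all j, with g the null
# deviance gradient and mu the constraint multiplier; the minimal feasible
# lambda is (max g - min g)/2.
zs_lambda_grid <- function(X, y, covariates = NULL, nlambda = 100,
                           lambda_min_ratio = 1e-4) {
  n <- nrow(X)
  if (is.null(covariates)) {
    p0 <- rep(mean(y), n)
  } else {
    p0 <- glm(y ~ ., data = as.data.frame(covariates),
              family = binomial())$fitted.values
  }
  g <- drop(crossprod(X, y - p0)) / n
  lambda_max <- (max(g) - min(g)) / 2 * 1.000001
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = nlambda))
}

#' Cross-validated penalty selection for the zero-sum lasso
#'
#' Builds a descending log-spaced lambda grid from the smallest
#' all-zero-coefficient penalty down four decades (unless supplied), fits
#' the warm-started path on each training fold (folds stratified by
#' outcome), and returns the lambda minimizing mean held-out binomial
#' deviance.
#'
#' @inheritParams fit_zero_sum
#' @param n_folds number of CV folds (default 4).
#' @param lambda optional descending grid; computed if `NULL`.
#' @param nlambda grid length when computed.
#' @param seed RNG seed for the fold partition.
#' @return List with `lambda_min`, `lambda`, `cvm` (mean held-out
#'   deviance), `folds`.
#' @export
cv_lambda <- function(X, y, covariates = NULL, n_folds = 4, lambda = NULL,
                      nlambda = 100, seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (is.null(lambda))
    lambda <- zs_lambda_grid(X, y, covariates, nlambda = nlambda)
  folds <- with_seed(seed, stratified_folds(y, n_folds))
  # evaluate the grid in expanding chunks: the held-out deviance minimum
  # sits high on the path unless the signal is strong, and the deep
  # (near-saturated) tail is by far the most expensive to fit
  n_eval <- min(max(12, ceiling(length(lambda) / 4)), length(lambda))
  repeat {
    dev <- matrix(0, n_folds, n_eval)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      path <- fit_zero_sum(X[tr, , drop = FALSE], y[tr], lambda[seq_len(n_eval)],
                           covariates = if (is.null(covariates)) NULL else
                             covariates[tr, , drop = FALSE])
      eta <- X[!tr, , drop = FALSE] %*% path$beta
      eta <- sweep(eta, 2, path$intercept, `+`)
      if (!is.null(covariates))
        eta <- eta + as.matrix(covariates)[!tr, , drop = FALSE] %*% path$covariate_coef
      yv <- y[!tr]
      dev[f, ] <- colMeans(2 * (log1p(exp(-abs(eta))) + pmax(eta, 0) - yv * eta))
    }
    cvm <- colMeans(dev)
    if (which.min(cvm) < n_eval - 2 || n_eval == length(lambda)) break
    n_eval <- min(length(lambda), 2 * n_eval)
  }
  cvm <- c(cvm, rep(NA_real_, length(lambda) - n_eval))
  list(lambda_min = lambda[which.min(cvm[seq_len(n_eval)])], lambda = lambda,
       cvm = cvm, folds = folds)
}

#' Stability selection for the zero-sum log-ratio lasso
#'
#' Repeats the full selection procedure `n_runs` times: re-randomize the
#' stratified fold partition, pick `lambda_min` by cross-validated
#' deviance, refit on the full data at `lambda_min`, and record which
#' features carry nonzero coefficients. Features are ranked by selection
#' probability (fraction of runs selected), then by absolute mean
#' coefficient, then by id.
#'
#' @inheritParams cv_lambda
#' @param n_runs number of repeated CV runs (default 100).
#' @param null_permute if `TRUE`, the outcome is freshly and independently
#'   permuted at the start of every run (a per-run draw from the
#'   no-association null), giving the null reference distribution of the
#'   selection probabilities. With a single fixed permutation the full-data
#'   path would be identical across runs and the earliest-entering feature
#'   would look spuriously stable.
#' @return Object of class `stability_result`: data.frame with columns
#'   `feature`, `selection_probability`, `mean_coefficient`, `sign`,
#'   `n_runs`.
#' @export
stability_select <- function(X, y, covariates = NULL, n_runs = 100,
                             n_folds = 4, nlambda = 100, seed = 1,
                             null_permute = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  lambda <- zs_lambda_grid(X, y, covariates, nlambda = nlambda)
  sel <- numeric(ncol(X))
  coefs <- numeric(ncol(X))
  for (r in seq_len(n_runs)) {
    yr <- if (null_permute) {
      with_seed(stage_seed(seed, 900 + r), sample(y))
    } else y
    cv <- cv_lambda(X, yr, covariates, n_folds = n_folds, lambda = lambda,
                    seed = stage_seed(seed, 200 + r))
    # refit on the full data at lambda_min, warm-started down the grid head
    head_grid <- lambda[lambda >= cv$lambda_min]
    path <- fit_zero_sum(X, yr, head_grid, covariates = covariates)
    beta_min <- if (length(head_grid) == 1) path$beta else
      path$beta[, length(head_grid)]
    nz <- abs(beta_min) > 1e-8
    sel <- sel + nz
    coefs <- coefs + beta_min
  }
  stability_result(colnames(X) %||% paste0("V", seq_len(ncol(X))),
                   sel / n_runs, coefs / n_runs, n_runs,
                   method = "zero-sum log-ratio lasso")
}

# Shared constructor for ranked stability-selection tables.
stability_result <- function(feature, prob, mean_coef, n_runs, method) {
  df <- data.frame(feature = feature, selection_probability = prob,
                   mean_coefficient = mean_coef,
                   sign = ifelse(prob == 0 | abs(mean_coef) < 1e-12, "0",
                                 ifelse(mean_coef > 0, "+", "-")),
                   n_runs = n_runs, stringsAsFactors = FALSE)
  df <- df[order(-df$selection_probability, -abs(df$mean_coefficient),
                 df$feature), ]
  rownames(df) <- NULL
  structure(df, class = c("stability_result", "data.frame"), method = method)
}

#' @export
print.stability_result <- function(x, n = 10, ...) {
  cat(sprintf("Stability selection (%s), %d runs\n",
              attr(x, "method") %||% "lasso", x$n_runs[1]))
  print.data.frame(head(x, n), digits = 3)
  if (nrow(x) > n) cat(sprintf("... and %d more features\n", nrow(x) - n))
  invisible(x)
}
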