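#' Stability-selected logistic lasso for metabolite predictors
#'
#' Repeats, `n_repeats` times with fresh stratified fold partitions, a
#' 10-fold cross-validated logistic lasso (glmnet) over a shared
#' log-spaced lambda grid: the penalty minimizing mean held-out binomial
#' deviance is chosen, the 10 per-fold coefficient vectors at that
#' `lambda_min` are averaged, and a feature counts as selected in that
#' repeat when its averaged coefficient is nonzero. The clinical covariate
#' (PTCy-based prophylaxis) is included unpenalized (penalty factor 0) and
#' excluded from the ranking.
#'
#' @param X numeric matrix of log metabolite levels (noncollinear,
#'   from [prep_metabolome()]), samples in rows.
#' @param y binary outcome (0/1).
#' @param covariate binary covariate vector (1 = PTCy-based prophylaxis).
#' @param n_folds CV folds per repeat (default 10).
#' @param n_repeats number of random partitions (default 100).
#' @param nlambda lambda grid length.
#' @param seed RNG seed.
#' @param null_permute if `TRUE`, the outcome is freshly permuted at the
#'   start of every repeat (per-run null draw; see [stability_select()]).
#' @return A `stability_result` (see [stability_select()]) over the
#'   metabolites, with the mean covariate coefficient in attribute
#'   `"covariate_coef"`.
#' @export
logistic_lasso_stability <- function(X, y, covariate = NULL, n_folds = 10,
                                     n_repeats = 100, nlambda = 100,
                                     seed = 1, null_permute = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  has_cov <- !is.null(covariate)
  Xa <- if (has_cov) cbind(X, .covariate = as.numeric(covariate)) else X
  pf <- c(rep(1, ncol(X)), if (has_cov) 0)
  grid <- glmnet::glmnet(Xa, y, family = "binomial", penalty.factor = pf,
                         nlambda = nlambda)$lambda
  p <- ncol(X)
  sel <- numeric(p)
  coefs <- numeric(p)
  cov_coef <- 0
  for (r in seq_len(n_repeats)) {
    yr <- if (null_permute) {
      with_seed(stage_seed(seed, 900 + r), sample(y))
    } else y
    folds <- with_seed(stage_seed(seed, 300 + r), stratified_folds(yr, n_folds))
    fold_fits <- vector("list", n_folds)
    dev <- matrix(NA_real_, n_folds, length(grid))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(Xa[tr, , drop = FALSE], yr[tr], family = "binomial",
                            penalty.factor = pf, lambda = grid)
      fold_fits[[f]] <- fit
      eta <- predict(fit, Xa[!tr, , drop = FALSE], type = "link")
      yv <- yr[!tr]
      d <- 2 * (log1p(exp(-abs(eta))) + pmax(eta, 0) - yv * eta)
      dev[f, seq_len(ncol(eta))] <- colMeans(d)
    }
    cvm <- colMeans(dev)  # NA where a fold path stopped early
    lambda_min <- grid[which.min(cvm)]
    cmat <- vapply(fold_fits, function(fit)
      as.numeric(coef(fit, s = lambda_min))[-1], numeric(ncol(Xa)))
    avg <- rowMeans(cmat)
    sel <- sel + (abs(avg[seq_len(p)]) > 1e-12)
    coefs <- coefs + avg[seq_len(p)]
    if (has_cov) cov_coef <- cov_coef + avg[p + 1]
  }
  res <- stability_result(colnames(X) %||% paste0("M", seq_len(p)),
                          sel / n_repeats, coefs / n_repeats, n_repeats,
                          method = "cross-validated logistic lasso (glmnet)")
  attr(res, "covariate_coef") <- if (has_cov) cov_coef / n_repeats else NULL
  res
}

# One sparse PLS-DA fit on standardized X and centered class code yc.
# Per component: weight = soft-thresholded X'yc keeping the top-keepX
# magnitudes, normalized; scores; deflation of X (and yc).
splsda_core <- function(Xs, yc, keepX) {
  p <- ncol(Xs)
  k <- length(keepX)
  W <- P <- matrix(0, p, k)
  Tm <- matrix(0, nrow(Xs), k)
  Xd <- Xs
  yd <- yc
  for (h in seq_len(k)) {
    c_vec <- drop(crossprod(Xd, yd))
    if (all(c_vec == 0)) c_vec[1] <- 1e-12
    kx <- min(keepX[h], p)
    thr <- if (kx < p) sort(abs(c_vec), decreasing = TRUE)[kx + 1] else 0
    w <- sign(c_vec) * pmax(abs(c_vec) - thr, 0)
    w <- w / sqrt(sum(w^2))
    t_h <- drop(Xd %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) tt <- 1e-12
    p_h <- drop(crossprod(Xd, t_h)) / tt
    W[, h] <- w
    P[, h] <- p_h
    Tm[, h] <- t_h
    Xd <- Xd - tcrossprod(t_h, p_h)
    yd <- yd - t_h * sum(t_h * yd) / tt
  }
  R <- W %*% solve(crossprod(P, W))  # projection for new samples
  list(W = W, P = P, R = R, scores = Tm)
}

splsda_ber <- function(scores_train, y_train, scores_test, y_test) {
  lev <- sort(unique(y_train))
  centroids <- do.call(rbind, lapply(lev, function(l)
    colMeans(scores_train[y_train == l, , drop = FALSE])))
  d <- vapply(seq_along(lev), function(i)
    rowSums(sweep(scores_test, 2, centroids[i, ])^2), numeric(nrow(scores_test)))
  pred <- lev[max.col(-d)]
  mean(vapply(lev, function(l) mean(pred[y_test == l] != l), numeric(1)))
}

#' Sparse partial least squares discriminant analysis
#'
#' Two-class sPLS-DA with per-component soft-thresholded weight vectors
#' (unit L2 norm, at most `keepX` nonzero entries) and centroid-distance
#' classification on the latent scores. Tuning selects, sequentially per
#' component, the `keepX` (then the number of components) minimizing the
#' mean balanced error rate (BER) over `n_repeats` runs of stratified
#' `n_folds`-fold cross-validation.
#'
#' @param X numeric feature matrix (samples x variables); standardized
#'   internally.
#' @param y two-class outcome.
#' @param max_components maximum number of latent components (default 2).
#' @param keepX_grid candidate per-component variable counts.
#' @param n_folds,n_repeats CV folds and repeats for tuning.
#' @param seed RNG seed.
#' @param tune set `FALSE` to skip tuning and fit `max_components`
#'   components with the first `keepX_grid` value each.
#' @return Object of class `splsda_fit`: `loadings` (p x ncomp), `keepX`,
#'   `ncomp`, `ber` (tuned mean BER), `ber_sd` (Monte-Carlo sd),
#'   `ber_by_config` (tuning table), `scores`, plus internals for
#'   [predict.splsda_fit()].
#' @export
splsda <- function(X, y, max_components = 2, keepX_grid = c(5, 10, 20, 50),
                   n_folds = 4, n_repeats = 100, seed = 1, tune = TRUE) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) stopf("splsda requires exactly two classes")
  if (any(keepX_grid > ncol(X))) {
    warnf("keepX capped at %d variables", ncol(X))
    keepX_grid <- pmin(keepX_grid, ncol(X))
  }
  keepX_grid <- sort(unique(keepX_grid))
  yc0 <- as.numeric(y == lev[2])
  ber_cv <- function(keepX) {
    bers <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      folds <- with_seed(stage_seed(seed, 400 + r), stratified_folds(yc0, n_folds))
      b <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, sd)
        sdv[sdv == 0] <- 1
        Xtr <- scale(X[tr, , drop = FALSE], mu, sdv)
        Xte <- scale(X[!tr, , drop = FALSE], mu, sdv)
        yc <- yc0[tr] - mean(yc0[tr])
        fit <- splsda_core(Xtr, yc, keepX)
        sc_te <- Xte %*% fit$R
        b[f] <- splsda_ber(fit$scores, y[tr], sc_te, y[!tr])
      }
      bers[r] <- mean(b)
    }
    c(mean = mean(bers), sd = sd(bers))
  }

  tuning <- NULL
  if (tune) {
    keepX <- integer(0)
    best_by_comp <- numeric(0)
    for (h in seq_len(max_components)) {
      res <- t(vapply(keepX_grid, function(kx) ber_cv(c(keepX, kx)), numeric(2)))
      tuning <- rbind(tuning,
                      data.frame(component = h, keepX = keepX_grid,
                                 ber = res[, "mean"], ber_sd = res[, "sd"]))
      pick <- keepX_grid[which.min(res[, "mean"])]
      keepX <- c(keepX, pick)
      best_by_comp <- c(best_by_comp, min(res[, "mean"]))
    }
    ncomp <- which.min(best_by_comp)
    keepX <- keepX[seq_len(ncomp)]
    ber <- best_by_comp[ncomp]
    ber_sd <- tuning$ber_sd[tuning$component == ncomp &
                              tuning$keepX == keepX[ncomp]]
  } else {
    ncomp <- max_components
    keepX <- rep(keepX_grid[1], ncomp)
    bs <- ber_cv(keepX)
    ber <- bs["mean"]; ber_sd <- bs["sd"]
  }

  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, mu, sdv)
  fit <- splsda_core(Xs, yc0 - mean(yc0), keepX)
  loadings <- fit$W
  dimnames(loadings) <- list(colnames(X), paste0("comp", seq_len(ncomp)))
  centroids <- do.call(rbind, lapply(lev, function(l)
    colMeans(fit$scores[y == l, , drop = FALSE])))
  rownames(centroids) <- lev
  structure(list(loadings = loadings, keepX = keepX, ncomp = ncomp,
                 ber = unname(ber), ber_sd = unname(ber_sd),
                 ber_by_config = tuning, scores = fit$scores,
                 centroids = centroids, levels = lev, center = mu,
                 scale = sdv, R = fit$R, seed = seed),
            class = "splsda_fit")
}

#' @export
print.splsda_fit <- function(x, ...) {
  cat(sprintf("sPLS-DA: %d component(s), keepX = {%s}, BER = %.3f (sd %.3f)\n",
              x$ncomp, paste(x$keepX, collapse = ", "), x$ber, x$ber_sd))
  top <- order(-abs(x$loadings[, 1]))[seq_len(min(5, nrow(x$loadings)))]
  cat("  top component-1 loadings:",
      paste(sprintf("%s (%.2f)", rownames(x$loadings)[top],
                    x$loadings[top, 1]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.splsda_fit <- function(object, newx, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  sc <- scale(as.matrix(newx), object$center, object$scale) %*% object$R
  if (type == "scores") return(sc)
  d <- vapply(seq_along(object$levels), function(i)
    rowSums(sweep(sc, 2, object$centroids[i, ])^2), numeric(nrow(sc)))
  object$levels[max.col(-d)]
}

#' Principal component scores
#'
#' SVD-based PCA of a standardized matrix with a deterministic sign
#' convention: each component is flipped so its largest-magnitude loading
#' is positive.
#'
#' @param X numeric matrix (samples x variables), typically the
#'   standardized log metabolite matrix.
#' @param k number of components; truncated to the matrix rank with a
#'   warning.
#' @return List with `scores` (n x k), `explained` (variance fractions,
#'   length k) and `loadings` (p x k).
#' @export
pca_scores <- function(X, k = 2) {
  X <- as.matrix(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (k > rank) {
    warnf("rank is %d; returning %d components", rank, rank)
    k <- rank
  }
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  list(scores = scores,
       explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
       loadings = loadings)
}
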