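test_that("log-ratio features match hand-computed log proportions", {
  m <- matrix(c(2, 8, 0, 1, 4, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  X <- logratio_features(count_table(m), pseudocount = 0.5)
  expect_equal(unname(X[1, "a"]), log(2.5 / 11.5))
  expect_equal(unname(X[2, "c"]), log(5.5 / 11.5))
  expect_error(logratio_features(matrix(1:3, 3, 1,
                                        dimnames = list(letters[1:3], "g"))),
               "two features")
})

test_that("full shrinkage gives the exact null model", {
  set.seed(31)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rbinom(20, 1, 0.4)
  f <- fit_zero_sum(X, y, lambda = 50)
  expect_equal(unname(f$beta), rep(0, 4))
  expect_equal(f$intercept, qlogis(mean(y)), tolerance = 1e-6)
  expect_equal(f$deviance,
               -2 * sum(dbinom(y, 1, mean(y), log = TRUE)), tolerance = 1e-6)
})

test_that("the zero-sum constraint holds to 1e-6 on random problems", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30 + 5 * seed
    p <- 8 + seed
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
    lam <- fmtomics:::zs_lambda_grid(X, y, nlambda = 15)
    path <- fit_zero_sum(X, y, lam)
    expect_true(all(path$constraint_residual <= 1e-6))
    expect_true(all(abs(colSums(path$beta)) <= 1e-6))
  }
})

test_that("objective matches a generic constrained optimizer on a 3-feature toy", {
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(20, 1, plogis(X[, 1] - X[, 3]))
  lam <- 0.05
  objective <- function(b0, beta) {
    eta <- b0 + X %*% beta
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lam * sum(abs(beta))
  }
  fit <- fit_zero_sum(X, y, lam)
  # oracle: Nelder-Mead on the (b0, b1, b2) parameterization with
  # b3 = -b1 - b2 absorbing the constraint, multi-started
  oracle <- optim(c(0, 0, 0), function(par)
    objective(par[1], c(par[2], par[3], -par[2] - par[3])),
    control = list(maxit = 20000, reltol = 1e-12))
  set.seed(8)
  for (i in 1:20) {
    alt <- optim(oracle$par + rnorm(3, 0, 0.3), function(par)
      objective(par[1], c(par[2], par[3], -par[2] - par[3])),
      control = list(maxit = 20000, reltol = 1e-12))
    if (alt$value < oracle$value) oracle <- alt
  }
  expect_lt(abs(objective(fit$intercept, fit$beta) - oracle$value), 1e-4)
})

test_that("two-feature fits reduce to a univariate lasso on the difference", {
  set.seed(8)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(30, 1, plogis(X[, 1] - X[, 2]))
  lam <- 0.08
  fit <- fit_zero_sum(X, y, lam, control = list(tol = 1e-9, max_irls = 60))
  d <- X[, 1] - X[, 2]
  # beta = (b, -b): objective equals univariate lasso on (a-b) with 2*lambda
  uni <- optim(c(0, 0), function(par) {
    eta <- par[1] + d * par[2]
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + 2 * lam * abs(par[2])
  }, control = list(reltol = 1e-14, maxit = 10000))
  expect_equal(unname(fit$beta["a"]), uni$par[2], tolerance = 1e-4)
  expect_lt(abs(fit$beta["a"] + fit$beta["b"]), 1e-6)
})

test_that("predictions are invariant to per-sample count rescaling", {
  set.seed(33)
  counts <- matrix(rpois(200, 40) + 1, 10, 20,
                   dimnames = list(paste0("s", 1:10), paste0("g", 1:20)))
  y <- rbinom(10, 1, 0.5)
  if (length(unique(y)) == 1) y[1] <- 1 - y[1]
  X1 <- logratio_features(counts)
  scaled <- counts * rep(c(1, 10, 100, 7, 2), 2)
  X2 <- logratio_features(scaled)
  fit <- fit_zero_sum(X1, y, 0.05)
  expect_equal(predict(fit, X1), predict(fit, X2), tolerance = 1e-10)
})

test_that("unpenalized covariates stay in the model under heavy penalty", {
  set.seed(34)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  z <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * z))
  fit <- fit_zero_sum(X, y, lambda = 5, covariates = cbind(z))
  expect_equal(unname(fit$beta), rep(0, 5))
  expect_gt(fit$covariate_coef[1], 0.5)
})

test_that("cross-validation selects sensible penalties", {
  set.seed(35)
  n <- 60
  # strong single log-ratio signal -> interior lambda
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- rbinom(n, 1, plogis(2 * (X[, 1] - X[, 2])))
  cv <- cv_lambda(X, y, n_folds = 4, nlambda = 30, seed = 1)
  idx <- which(cv$lambda == cv$lambda_min)
  expect_gt(idx, 1)
  expect_lt(idx, 30)
  # grid of length 1 is returned as-is
  cv1 <- cv_lambda(X, y, n_folds = 4, lambda = 0.1, seed = 1)
  expect_equal(cv1$lambda_min, 0.1)
  # stratification failure raises an informative error
  expect_error(cv_lambda(X, c(1, rep(0, n - 1)), n_folds = 4, seed = 1),
               "stratify")
})

test_that("single-run stability probabilities are zero or one", {
  set.seed(36)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rbinom(40, 1, plogis(X[, 1] - X[, 5]))
  st <- stability_select(X, y, n_runs = 1, n_folds = 4, nlambda = 15, seed = 4)
  expect_true(all(st$selection_probability %in% c(0, 1)))
  expect_true(all(st$sign[st$selection_probability == 0] == "0"))
  # ranking: probability desc, then |mean coefficient| desc
  expect_true(all(diff(st$selection_probability) <= 0))
})

test_that("sparsity is monotone along the path (weak check)", {
  set.seed(37)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- rbinom(50, 1, plogis(X[, 1] - X[, 2]))
  lam <- fmtomics:::zs_lambda_grid(X, y, nlambda = 12)
  path <- fit_zero_sum(X, y, lam)
  nz <- colSums(abs(path$beta) > 1e-8)
  violations <- sum(diff(nz) < 0)
  if (violations > 0) {
    warning(sprintf("%d sparsity monotonicity violations along path", violations))
  }
  expect_lte(violations, 2)
})
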