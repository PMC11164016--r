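test_that("anchor median-of-ratios adjustment inverts a pure batch shift", {
  m <- make_batch_metab(seed = 41)
  adj <- batch_adjust(m)
  # anchor reruns equal their reference originals after adjustment
  ap <- m$anchor_pairs
  expect_equal(adj$intensities[ap$target, ], adj$intensities[ap$reference, ],
               ignore_attr = TRUE, tolerance = 1e-12)
  # reference batch untouched
  ref <- m$batch == "reference"
  expect_equal(adj$intensities[ref, ], m$intensities[ref, ])
})

test_that("per-metabolite factor is the median of clean anchor ratios", {
  x <- rbind(R1 = c(2, 10), R2 = c(4, 0), R3 = c(6, 30),
             T1 = c(1, 5), T2 = c(2, 0), T3 = c(3, 10), Tx = c(100, 7))
  colnames(x) <- c("m1", "m2")
  m <- metabolite_matrix(x, batch = c(rep("reference", 3), rep("target", 4)),
                         anchor_pairs = data.frame(
                           reference = c("R1", "R2", "R3"),
                           target = c("T1", "T2", "T3")))
  adj <- batch_adjust(m, min_pairs = 1)
  f <- attr(adj, "batch_factors")
  # m1 ratios are {2, 2, 2} -> factor 2; m2 excludes the zero pair: {2, 3}
  expect_equal(unname(f["m1"]), 2)
  expect_equal(unname(f["m2"]), 2.5)
  # zeros stay zero after adjustment
  expect_equal(unname(adj$intensities["T2", "m2"]), 0)
  # a metabolite below min_pairs clean anchors falls back to the global factor
  adj2 <- batch_adjust(m, min_pairs = 3)
  expect_equal(unname(attr(adj2, "batch_factors")["m2"]), 2)
  expect_true("m2" %in% attr(adj2, "fallback_metabolites"))
})

test_that("batch adjustment preserves within-batch rank order", {
  m <- make_batch_metab(seed = 43, zeros = 5)
  adj <- batch_adjust(m)
  tgt <- which(m$batch == "target")
  for (j in seq_len(ncol(m$intensities))) {
    expect_equal(order(m$intensities[tgt, j]), order(adj$intensities[tgt, j]))
  }
})

test_that("detection filter uses a strict >25% rule and matches brute force", {
  x <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), paste0("m", 1:3)))
  x[1, 2] <- 0              # 25% zeros -> kept (not strictly greater)
  x[c(1, 2), 3] <- 0        # 50% zeros -> dropped
  m <- metabolite_matrix(x, batch = rep("reference", 4))
  kept <- detection_filter(m, max_undetected = 0.25)
  expect_equal(colnames(kept$intensities), c("m1", "m2"))
  # brute-force oracle on a random zero-inflated matrix
  set.seed(44)
  z <- matrix(rlnorm(200), 10, 20,
              dimnames = list(paste0("s", 1:10), sprintf("m%02d", 1:20)))
  z[runif(200) < 0.3] <- 0
  mm <- metabolite_matrix(z, batch = rep("reference", 10))
  kept2 <- detection_filter(mm, max_undetected = 0.25)
  oracle <- colnames(z)[vapply(seq_len(20), function(j)
    mean(z[, j] == 0) <= 0.25, logical(1))]
  expect_equal(colnames(kept2$intensities), oracle)
})

test_that("collinearity pruning keeps one representative per component", {
  set.seed(45)
  n <- 30
  base <- rlnorm(n, 10, 1)
  x <- cbind(A = base, B = base * 1.001, C = rlnorm(n, 10, 1))
  rownames(x) <- paste0("s", 1:n)
  m <- metabolite_matrix(x, batch = rep("reference", n))
  pr <- prune_collinear(m, rho_max = 0.5)
  # perfectly duplicated pair: one kept, one dropped, C untouched
  expect_equal(ncol(pr$matrix$intensities), 2)
  expect_true("C" %in% colnames(pr$matrix$intensities))
  expect_length(pr$dropped, 1)
  # rho_max = 1 prunes nothing (spearman rho <= 1 never strictly greater)
  pr1 <- prune_collinear(m, rho_max = 1)
  expect_equal(ncol(pr1$matrix$intensities), 3)
})

test_that("a correlation chain collapses to a single representative", {
  set.seed(1)
  n <- 60
  z1 <- rnorm(n)
  a <- z1
  b <- 0.75 * z1 + sqrt(1 - 0.75^2) * rnorm(n)
  cc <- 0.75 * b + sqrt(1 - 0.75^2) * rnorm(n)
  x <- exp(cbind(A = a, B = b, C = cc) + 10)
  rownames(x) <- paste0("s", 1:n)
  m <- metabolite_matrix(x, batch = rep("reference", n))
  # adjacency is A~B and B~C only: a genuine chain
  rho <- cor(x, method = "spearman")
  expect_gt(rho["A", "B"], 0.5)
  expect_gt(rho["B", "C"], 0.5)
  expect_lt(rho["A", "C"], 0.5)
  pr <- prune_collinear(m, rho_max = 0.5)
  expect_equal(ncol(pr$matrix$intensities), 1)
  # all dropped members map to the single kept representative
  expect_equal(unname(unique(pr$dropped)), colnames(pr$matrix$intensities))
})

test_that("pruning keeps exactly one member per graph component (BFS oracle)", {
  set.seed(47)
  x <- matrix(rlnorm(40 * 15, 10, 1), 40, 15,
              dimnames = list(paste0("s", 1:40), sprintf("m%02d", 1:15)))
  f <- rnorm(40)
  for (j in 1:5) x[, j] <- exp(0.9 * f + 0.3 * rnorm(40) + 10)
  m <- metabolite_matrix(x, batch = rep("reference", 40))
  pr <- prune_collinear(m, rho_max = 0.5)
  kept <- colnames(pr$matrix$intensities)
  # independent BFS over the rho > 0.5 graph
  adj <- cor(x, method = "spearman") > 0.5
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, 15)
  cid <- 0
  for (start in 1:15) {
    if (!is.na(comp[start])) next
    cid <- cid + 1
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  ids <- colnames(x)
  for (cc in unique(comp)) {
    members <- ids[comp == cc]
    expect_equal(sum(members %in% kept), 1)
    # dropped members map to the representative of their own component
    for (d in setdiff(members, kept)) {
      expect_true(pr$dropped[[d]] %in% members)
    }
  }
})

test_that("half-minimum imputation replaces zeros by half the minimum nonzero", {
  x <- matrix(c(0, 4, 8,
                2, 2, 2), 3, 2,
              dimnames = list(paste0("s", 1:3), c("m1", "m2")))
  m <- metabolite_matrix(x, batch = rep("reference", 3))
  imp <- half_min_impute(m)
  expect_equal(unname(imp$intensities[, "m1"]), c(2, 4, 8))
  expect_equal(imp$intensities[, "m2"], x[, "m2"])  # no zeros -> identity
  # brute-force oracle on a random matrix
  set.seed(48)
  z <- matrix(rlnorm(100), 10, 10,
              dimnames = list(paste0("s", 1:10), sprintf("m%02d", 1:10)))
  z[runif(100) < 0.2] <- 0
  z[1, ] <- pmax(z[1, ], 0.01)  # ensure no all-zero column
  mm <- half_min_impute(metabolite_matrix(z, batch = rep("reference", 10)))
  for (j in 1:10) {
    nz <- z[, j][z[, j] > 0]
    expect_equal(unname(mm$intensities[, j]),
                 unname(ifelse(z[, j] == 0, min(nz) / 2, z[, j])))
  }
  z2 <- z; z2[, 3] <- 0
  expect_error(half_min_impute(metabolite_matrix(z2, batch = rep("reference", 10))),
               "all-zero")
})

test_that("log standardization matches hand computation and validates input", {
  x <- matrix(c(exp(1), exp(2)), 2, 1, dimnames = list(c("s1", "s2"), "m1"))
  ls <- log_standardize(metabolite_matrix(x, batch = rep("reference", 2)))
  expect_equal(unname(ls[, 1]), c(-1, 1) / sqrt(2))  # sd with n-1 denominator
  raw <- log_standardize(metabolite_matrix(x, batch = rep("reference", 2)),
                         standardize = FALSE)
  expect_equal(unname(raw[, 1]), c(1, 2))
  expect_error(log_standardize(matrix(c(1, 1), 2, 1,
                                      dimnames = list(c("a", "b"), "m")),
                               standardize = TRUE), "constant")
  expect_error(log_standardize(matrix(c(0, 1), 2, 1,
                                      dimnames = list(c("a", "b"), "m"))),
               "positive")
})

test_that("prep stages are idempotent where re-application is meaningful", {
  m <- make_batch_metab(seed = 49, zeros = 10)
  det <- detection_filter(m, 0.25)
  expect_equal(detection_filter(det, 0.25)$intensities, det$intensities)
  imp <- half_min_impute(det)
  expect_equal(half_min_impute(imp)$intensities, imp$intensities)
  pr <- prune_collinear(imp, rho_max = 0.5)
  pr2 <- prune_collinear(pr$matrix, rho_max = 0.5)
  expect_equal(colnames(pr2$matrix$intensities), colnames(pr$matrix$intensities))
})
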