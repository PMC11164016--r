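test_that("clr transform has the defining closed-form properties", {
  # uniform composition maps to zero
  u <- clr_transform(matrix(c(1, 1, 1, 1), 1, 4,
                            dimnames = list("s", letters[1:4])))
  expect_equal(unname(u[1, ]), rep(0, 4))
  # (1, 3) with no pseudocount -> (-log(3)/2, +log(3)/2)
  v <- clr_transform(matrix(c(1, 3), 1, 2, dimnames = list("s", c("a", "b"))),
                     pseudocount = 0)
  expect_equal(unname(v[1, ]), c(-log(3) / 2, log(3) / 2))
  # scale invariance and zero row sums
  set.seed(4)
  x <- matrix(rpois(60, 20) + 1, 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  expect_equal(clr_transform(x, 0), clr_transform(10 * x, 0))
  expect_true(all(abs(rowSums(clr_transform(x))) < 1e-9))
  expect_error(clr_transform(rbind(x, s0 = 0)), "all-zero")
  expect_error(clr_transform(matrix(c(0, 1), 1, 2,
                                    dimnames = list("s", c("a", "b"))),
                             pseudocount = 0), "pseudocount")
})

test_that("Aitchison distance is Euclidean on clr rows", {
  # clr rows (0,0) and (-a,a) are distance a*sqrt(2) apart
  a <- 0.7
  m <- rbind(s1 = c(0, 0), s2 = c(-a, a))
  expect_equal(unname(as.matrix(aitchison_distance(m))[1, 2]), a * sqrt(2))
  # identical rows -> 0; brute force agreement on random compositions
  set.seed(5)
  x <- matrix(rpois(20, 30) + 1, 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  d <- as.matrix(aitchison_distance(x, pseudocount = 0))
  cl <- clr_transform(x, 0)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], sqrt(sum((cl[i, ] - cl[j, ])^2)))
  }
  expect_equal(d[2, 2], 0)
})

test_that("Aitchison distance agrees with vegan's implementation", {
  set.seed(6)
  x <- matrix(rpois(40, 25) + 1, 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  ours <- as.matrix(aitchison_distance(x, pseudocount = 0))
  ref <- as.matrix(vegan::vegdist(x, method = "aitchison"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("PCoA recovers planar configurations and bounds explained variance", {
  set.seed(8)
  pts <- cbind(runif(12), runif(12))
  rownames(pts) <- paste0("s", 1:12)
  d <- dist(pts)
  res <- pcoa(d, k = 2)
  # distances reproduced exactly in full dimension (Procrustes-free check)
  expect_equal(as.matrix(dist(res$coordinates)), as.matrix(d),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(sum(res$explained) <= 1 + 1e-12)
  # two points at distance a -> coordinates +- a/2
  d2 <- dist(matrix(c(0, 3), 2, 1, dimnames = list(c("a", "b"), NULL)))
  expect_warning(r2 <- pcoa(d2, k = 2), "positive eigenvalues")
  expect_equal(sort(unname(r2$coordinates[, 1])), c(-1.5, 1.5))
})

test_that("PERMANOVA pseudo-F and R2 match vegan::adonis2", {
  set.seed(9)
  x <- rbind(matrix(rnorm(30), 10, 3), matrix(rnorm(30, 1), 10, 3))
  rownames(x) <- paste0("s", 1:20)
  g <- rep(c("A", "B"), each = 10)
  d <- dist(x)
  ours <- permanova(d, g, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$r2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA p agrees with exhaustive enumeration at n = 6", {
  set.seed(10)
  x <- matrix(rnorm(12), 6, 2)
  rownames(x) <- paste0("s", 1:6)
  d <- dist(x)
  g <- rep(c("A", "B"), each = 3)
  # exact permutation distribution over all 20 label splits
  D2 <- as.matrix(d)^2
  f_of <- function(lab) {
    ssw <- sum(vapply(unique(lab), function(l) {
      z <- lab == l
      sum(D2[z, z]) / (2 * sum(z))
    }, numeric(1)))
    sst <- sum(D2) / 12
    ((sst - ssw) / 1) / (ssw / 4)
  }
  splits <- combn(6, 3)
  f_all <- apply(splits, 2, function(idx) {
    lab <- rep("B", 6); lab[idx] <- "A"; f_of(lab)
  })
  f_obs <- f_of(g)
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova(d, g, n_perm = 999, seed = 3)
  expect_lt(abs(res$p_value - p_exact), 0.03)
})

test_that("PERMANOVA behaves at the null and at saturation", {
  set.seed(11)
  # identical point clouds -> large p
  x <- rbind(m <- matrix(rnorm(16), 8, 2), m)
  rownames(x) <- paste0("s", 1:16)
  res <- permanova(dist(x), rep(c("A", "B"), each = 8), n_perm = 199, seed = 2)
  expect_gte(res$p_value, 0.5)
  # well-separated clouds -> minimum attainable p
  y <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 30), 10, 2))
  rownames(y) <- paste0("s", 1:20)
  res2 <- permanova(dist(y), rep(c("A", "B"), each = 10), n_perm = 999, seed = 2)
  expect_equal(res2$p_value, 1 / 1000)
  expect_error(permanova(dist(y), rep("A", 20)), "two groups")
})

test_that("two-group comparison matches wilcox.test and Bonferroni arithmetic", {
  expect_equal(group_compare(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$p_value, 1)
  # exact enumeration agreement for 4 vs 4 distinct values
  set.seed(12)
  v <- sample(seq(0.1, 0.8, by = 0.1))
  g <- rep(c("a", "b"), each = 4)
  res <- group_compare(v, g)
  ref <- wilcox.test(v[g == "a"], v[g == "b"], exact = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))
  # Bonferroni: p times m, capped at 1
  expect_equal(group_compare(v, g, correction = "bonferroni", m = 3)$p_adj,
               min(1, ref$p.value * 3))
  expect_equal(group_compare(rep(5, 6), rep(c("a", "b"), 3))$p_value, 1)
})

test_that("Ward grouping recovers separated blobs and is order invariant", {
  set.seed(13)
  x <- rbind(matrix(rnorm(30, 0), 10, 3), matrix(rnorm(30, 8), 10, 3),
             matrix(rnorm(30, -8), 10, 3))
  rownames(x) <- paste0("s", 1:30)
  lab <- ward_groups(x, n_groups = 3, scale = "none")
  truth <- rep(1:3, each = 10)
  expect_equal(length(unique(paste(lab, truth))), 3)  # bijection up to relabel
  # permuted rows give the same partition up to relabeling
  perm <- sample(30)
  lab2 <- ward_groups(x[perm, ], n_groups = 3, scale = "none")
  expect_equal(length(unique(paste(lab2, truth[perm]))), 3)
  # n_groups = n -> singletons
  expect_equal(length(unique(ward_groups(x[1:5, ], n_groups = 5, scale = "none"))), 5)
  expect_error(ward_groups(x[1:3, ], n_groups = 4), "exceeds")
})
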