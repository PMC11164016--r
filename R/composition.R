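#' Centered log-ratio transform
#'
#' Adds a pseudocount to each entry, closes rows to proportions, takes
#' logs, and centers each row at its mean log, so every output row sums to
#' zero. The transform is invariant to per-row rescaling of the input.
#'
#' @param x a [count_table()], or a nonnegative matrix with samples in rows.
#' @param pseudocount value added to every entry before closure; must be
#'   positive if `x` contains zeros. For count data the Bayes-multiplicative
#'   default 0.5 is used; for proportion-scale input (e.g. topic
#'   abundances) pass a small floor such as `1e-6`.
#' @return A numeric matrix of clr values, same dimnames as the input.
#' @examples
#' clr_transform(matrix(c(1, 3), 1, 2,
#'                      dimnames = list("s", c("a", "b"))), pseudocount = 0)
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  if (inherits(x, "count_table")) x <- x$counts
  x <- as.matrix(x)
  if (any(x < 0)) stopf("clr input must be nonnegative")
  zero_rows <- rowSums(x) == 0
  if (any(zero_rows))
    stopf("all-zero row(s): %s",
          paste(head(rownames(x)[zero_rows] %||% which(zero_rows), 3), collapse = ", "))
  if (pseudocount <= 0 && any(x == 0))
    stopf("zeros present: pseudocount must be > 0")
  x <- x + pseudocount
  lp <- log(x / rowSums(x))
  lp - rowMeans(lp)
}

#' Aitchison distance
#'
#' Pairwise Euclidean distance between clr-transformed compositions. Input
#' may be raw counts/compositions (then [clr_transform()] is applied with
#' `pseudocount`) or an already clr-transformed matrix (rows summing to 0).
#'
#' @inheritParams clr_transform
#' @return A [stats::dist] object.
#' @export
aitchison_distance <- function(x, pseudocount = 0.5) {
  if (inherits(x, "count_table")) x <- x$counts
  x <- as.matrix(x)
  already_clr <- all(abs(rowSums(x)) < 1e-6) && any(x < 0)
  m <- if (already_clr) x else clr_transform(x, pseudocount)
  dist(m)
}

#' Principal coordinates analysis
#'
#' Classical metric MDS: double-centering of the squared distance matrix
#' and eigendecomposition, axes ordered by eigenvalue. The explained
#' fraction of axis i is `lambda_i / sum(positive lambda)`.
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @param k number of axes requested; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return List with `coordinates` (n x k), `explained` (length k) and
#'   `eig` (all eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.dist(d)
  n <- attr(d, "Size")
  res <- cmdscale(d, k = min(k, n - 1), eig = TRUE)
  pos <- res$eig[res$eig > 1e-8 * max(abs(res$eig))]
  if (k > length(pos)) {
    warnf("only %d positive eigenvalues; returning %d axes", length(pos), length(pos))
    k <- length(pos)
  }
  coords <- res$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       explained = res$eig[seq_len(k)] / sum(pos),
       eig = res$eig)
}

# Sum over groups of within-group mean squared distances: for group g with
# indicator z, SS_g = (z' D2 z) / (2 n_g); vectorized over many label
# permutations at once.
permanova_ss_within <- function(D2, labels_mat) {
  lev <- unique(as.vector(labels_mat[, 1]))
  ss <- numeric(ncol(labels_mat))
  for (g in lev) {
    Z <- (labels_mat == g) * 1
    ng <- colSums(Z)
    ss <- ss + colSums(Z * (D2 %*% Z)) / (2 * ng)
  }
  ss
}

#' Permutational multivariate ANOVA (one factor)
#'
#' Anderson's pseudo-F computed directly from the distance matrix:
#' `SS_total = sum(d^2)/n`, `SS_within = sum_g sum_{i<j in g} d_ij^2/n_g`,
#' `F = (SS_among/(a-1)) / (SS_within/(n-a))`. The permutation p-value is
#' `(1 + #{F_perm >= F_obs}) / (n_perm + 1)`, permuting raw labels (freely
#' exchangeable, no strata).
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @param groups group labels, length n, at least two nonempty groups.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return Object of class `permanova`: list with `pseudo_F`, `r2`,
#'   `p_value`, `n_perm`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(as.dist(d))
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) stopf("groups length %d != %d samples", length(groups), n)
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least two groups")
  if (any(tab == 0)) stopf("empty group")
  a <- length(tab)
  D2 <- D^2
  ss_total <- sum(D2) / (2 * n)
  ss_within <- permanova_ss_within(D2, matrix(groups, ncol = 1))
  ss_among <- ss_total - ss_within
  f_obs <- (ss_among / (a - 1)) / (ss_within / (n - a))
  perm_labels <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(groups), character(n))
  })
  f_perm <- {
    ssw <- permanova_ss_within(D2, perm_labels)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  structure(list(pseudo_F = f_obs, r2 = ss_among / ss_total, p_value = p,
                 n_perm = n_perm, df = c(among = a - 1, within = n - a)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$r2, x$p_value, x$n_perm))
  invisible(x)
}

#' Two-group comparison with optional Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum test (exact when both groups have at most 10
#' observations and no ties; normal approximation with tie correction
#' otherwise). With `correction = "bonferroni"` the p-value is multiplied
#' by `m` and capped at 1. A pooled-constant input returns p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups two-level grouping of `values`.
#' @param correction `"none"` or `"bonferroni"`.
#' @param m number of comparisons for the Bonferroni family.
#' @return List with `statistic` (W), `p_value` and `p_adj`.
#' @export
group_compare <- function(values, groups, correction = c("none", "bonferroni"),
                          m = 1) {
  correction <- match.arg(correction)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("group_compare needs exactly two groups")
  if (any(table(groups) == 0)) stopf("each group needs at least one observation")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(unique(values)) == 1) {
    w <- length(x) * length(y) / 2
    p <- 1
  } else {
    exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(values))
    ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
    w <- unname(ht$statistic)
    p <- min(1, ht$p.value)
  }
  p_adj <- if (correction == "bonferroni") min(1, p * m) else p
  list(statistic = w, p_value = p, p_adj = p_adj)
}

#' Ward hierarchical grouping
#'
#' Agglomerative clustering with the classic `ward.D` update on Euclidean
#' distances after the requested scaling, cut into `n_groups` groups
#' (the sample-group A/B/C construction on topic-abundance profiles).
#'
#' @param x numeric matrix (observations in rows).
#' @param n_groups number of groups to cut the tree into.
#' @param scale `"row"` (center/scale each row), `"column"`, or `"none"`.
#' @return Integer group labels named by rownames, with the `hclust` tree
#'   in attribute `"tree"`.
#' @export
ward_groups <- function(x, n_groups = 3, scale = c("row", "column", "none")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("ward_groups requires finite input")
  if (n_groups > nrow(x)) stopf("n_groups (%d) exceeds %d rows", n_groups, nrow(x))
  xs <- switch(scale,
               row = t(scale(t(x))),
               column = scale(x),
               none = x)
  xs[is.nan(xs)] <- 0  # zero-variance rows/columns scale to 0
  hc <- hclust(dist(xs), method = "ward.D")
  labels <- cutree(hc, k = n_groups)
  attr(labels, "tree") <- hc
  labels
}
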