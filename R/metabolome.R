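#' Serum metabolite intensity matrix
#'
#' Container for nonnegative untargeted-metabolomics intensities (0 = not
#' detected) with per-sample batch labels and optional anchor pairs
#' (identical samples run in both batches) and pathway annotations.
#'
#' @param intensities numeric matrix, samples in rows, metabolites in
#'   columns, with dimnames.
#' @param batch per-sample label, `"reference"` or `"target"`.
#' @param anchor_pairs optional `data.frame` with columns `reference` and
#'   `target` naming the paired sample ids in each batch.
#' @param pathway optional per-metabolite annotation vector.
#' @return Object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(intensities, batch, anchor_pairs = NULL,
                              pathway = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stopf("intensities need sample and metabolite names")
  if (any(intensities < 0) || any(is.na(intensities)))
    stopf("intensities must be nonnegative and non-missing")
  batch <- as.character(batch)
  if (length(batch) != nrow(intensities))
    stopf("batch must have one label per sample")
  if (!all(batch %in% c("reference", "target")))
    stopf("batch labels must be 'reference' or 'target'")
  if (!is.null(anchor_pairs)) {
    ids <- rownames(intensities)
    bad_r <- setdiff(anchor_pairs$reference, ids[batch == "reference"])
    bad_t <- setdiff(anchor_pairs$target, ids[batch == "target"])
    if (length(bad_r) || length(bad_t))
      stopf("anchor pairs refer to missing samples: %s",
            paste(head(c(bad_r, bad_t), 3), collapse = ", "))
  }
  structure(list(intensities = intensities, batch = batch,
                 anchor_pairs = anchor_pairs, pathway = pathway),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("metabolite_matrix: %d samples x %d metabolites (%d reference / %d target)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$batch == "reference"), sum(x$batch == "target")))
  if (!is.null(x$anchor_pairs))
    cat(sprintf("  %d anchor pairs\n", nrow(x$anchor_pairs)))
  cat(sprintf("  non-detection rate: %.1f%%\n", 100 * mean(x$intensities == 0)))
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$intensities)

subset_metabolites <- function(m, keep) {
  metabolite_matrix(m$intensities[, keep, drop = FALSE], m$batch,
                    anchor_pairs = m$anchor_pairs,
                    pathway = if (!is.null(m$pathway)) m$pathway[keep])
}

#' Anchor-sample median-of-ratios batch adjustment
#'
#' For each metabolite, computes the median over anchor pairs of the
#' reference/target intensity ratio (pairs where either value is
#' undetected are excluded) and multiplies every target-batch value by that
#' factor. The reference batch is unchanged and zeros remain zero. With
#' `mode = "per_metabolite"` (default) a metabolite with fewer than
#' `min_pairs` clean anchor pairs falls back to the global median ratio
#' across all metabolites' clean pairs; `mode = "global"` applies the
#' global factor to every metabolite.
#'
#' @param m a [metabolite_matrix()] with anchor pairs.
#' @param mode `"per_metabolite"` or `"global"`.
#' @param min_pairs minimum clean anchor pairs before the per-metabolite
#'   factor is trusted.
#' @return The adjusted [metabolite_matrix()]; the factors used are in
#'   attribute `"batch_factors"` and fallback metabolites in
#'   `"fallback_metabolites"`.
#' @export
batch_adjust <- function(m, mode = c("per_metabolite", "global"),
                         min_pairs = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "metabolite_matrix"))
  if (is.null(m$anchor_pairs) || !nrow(m$anchor_pairs))
    stopf("batch_adjust requires anchor pairs")
  xr <- m$intensities[m$anchor_pairs$reference, , drop = FALSE]
  yt <- m$intensities[m$anchor_pairs$target, , drop = FALSE]
  clean <- xr > 0 & yt > 0
  if (!any(clean)) stopf("no usable anchor pairs for any metabolite")
  ratio <- ifelse(clean, xr / yt, NA_real_)
  global_factor <- median(ratio[clean])
  per_met <- apply(ratio, 2, median, na.rm = TRUE)
  n_clean <- colSums(clean)
  fallback <- n_clean < min_pairs
  factors <- if (mode == "global") {
    rep(global_factor, ncol(m$intensities))
  } else {
    ifelse(fallback, global_factor, per_met)
  }
  names(factors) <- colnames(m$intensities)
  out <- m$intensities
  tgt <- m$batch == "target"
  out[tgt, ] <- sweep(out[tgt, , drop = FALSE], 2, factors, `*`)
  res <- metabolite_matrix(out, m$batch, anchor_pairs = m$anchor_pairs,
                           pathway = m$pathway)
  attr(res, "batch_factors") <- factors
  attr(res, "fallback_metabolites") <-
    if (mode == "per_metabolite") names(factors)[fallback] else character(0)
  res
}

#' Drop metabolites with too many non-detections
#'
#' Removes metabolites whose fraction of zero (undetected) values is
#' strictly greater than `max_undetected` (default: "undetectable levels
#' in >25% of the samples").
#'
#' @param m a [metabolite_matrix()].
#' @param max_undetected maximum tolerated zero fraction (inclusive).
#' @return The filtered [metabolite_matrix()].
#' @export
detection_filter <- function(m, max_undetected = 0.25) {
  stopifnot(inherits(m, "metabolite_matrix"))
  keep <- colMeans(m$intensities == 0) <= max_undetected
  subset_metabolites(m, which(keep))
}

#' Prune collinear metabolites
#'
#' Builds a graph with an edge between metabolites whose Spearman
#' correlation exceeds `rho_max` (signed by default; absolute with
#' `absolute = TRUE`), and keeps one representative per connected
#' component: the member with the highest variance of log values (zeros
#' half-minimum-substituted for this ranking only), ties broken
#' lexicographically.
#'
#' @param m a [metabolite_matrix()] with at least two samples.
#' @param rho_max correlation threshold (exclusive), default 0.5.
#' @param absolute use `|rho|` instead of signed rho.
#' @return List with `matrix` (pruned [metabolite_matrix()]) and `dropped`
#'   (named character vector mapping each dropped metabolite to its kept
#'   representative).
#' @export
prune_collinear <- function(m, rho_max = 0.5, absolute = FALSE) {
  stopifnot(inherits(m, "metabolite_matrix"))
  x <- m$intensities
  if (nrow(x) < 2) stopf("prune_collinear needs at least two samples")
  const <- apply(x, 2, function(v) max(v) - min(v)) == 0
  if (any(const))
    warnf("%d constant metabolite(s): correlations treated as 0", sum(const))
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  edge <- if (absolute) abs(rho) > rho_max else rho > rho_max
  diag(edge) <- FALSE

  # connected components by union-find
  p <- ncol(x)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(p - 1)) {
    js <- which(edge[i, (i + 1):p]) + i
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(p), find, integer(1))

  # representative: highest log-variance (zeros -> half-minimum for ranking)
  xlog <- apply(x, 2, function(v) {
    nz <- v[v > 0]
    if (!length(nz)) return(rep(0, length(v)))
    log(ifelse(v == 0, min(nz) / 2, v))
  })
  lv <- apply(xlog, 2, var)
  ids <- colnames(x)
  keep <- logical(p)
  dropped <- character(0)
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    rep_i <- members[order(-lv[members], ids[members])][1]
    keep[rep_i] <- TRUE
    if (length(members) > 1) {
      d <- setdiff(members, rep_i)
      dropped <- c(dropped, setNames(rep(ids[rep_i], length(d)), ids[d]))
    }
  }
  kept_m <- subset_metabolites(m, which(keep))
  # representatives from different components may still correlate; log it
  if (sum(keep) > 1) {
    rk <- rho[keep, keep]
    over <- if (absolute) abs(rk) > rho_max else rk > rho_max
    diag(over) <- FALSE
    if (any(over))
      message(sprintf("note: %d retained cross-component pair(s) with rho > %.2f",
                      sum(over) / 2, rho_max))
  }
  list(matrix = kept_m, dropped = dropped)
}

#' Half-minimum imputation of non-detections
#'
#' Replaces zeros in each metabolite by half its minimum nonzero value
#' across all samples.
#'
#' @param m a [metabolite_matrix()]; every metabolite must have at least
#'   one nonzero value (guaranteed after [detection_filter()]).
#' @return The imputed [metabolite_matrix()].
#' @export
half_min_impute <- function(m) {
  stopifnot(inherits(m, "metabolite_matrix"))
  x <- m$intensities
  all_zero <- colSums(x > 0) == 0
  if (any(all_zero))
    stopf("all-zero metabolite(s): %s",
          paste(head(colnames(x)[all_zero], 3), collapse = ", "))
  for (j in which(colSums(x == 0) > 0)) {
    x[x[, j] == 0, j] <- min(x[x[, j] > 0, j]) / 2
  }
  metabolite_matrix(x, m$batch, anchor_pairs = m$anchor_pairs,
                    pathway = m$pathway)
}

#' Log transform and per-metabolite standardization
#'
#' Natural log of strictly positive intensities; with
#' `standardize = TRUE`, each metabolite is centered and scaled to unit
#' standard deviation (denominator n - 1).
#'
#' @param m a [metabolite_matrix()] or positive matrix.
#' @param standardize center/scale per metabolite?
#' @return Numeric matrix of (standardized) log intensities.
#' @export
log_standardize <- function(m, standardize = TRUE) {
  x <- if (inherits(m, "metabolite_matrix")) m$intensities else as.matrix(m)
  if (any(x <= 0)) stopf("log_standardize requires strictly positive values (impute first)")
  lx <- log(x)
  if (!standardize) return(lx)
  sds <- apply(lx, 2, sd)
  if (any(sds == 0))
    stopf("constant metabolite(s) cannot be standardized: %s",
          paste(head(colnames(lx)[sds == 0], 3), collapse = ", "))
  scale(lx)
}

#' Full metabolome preprocessing chain
#'
#' Applies, in order: anchor-based batch adjustment, detection filter,
#' collinearity pruning, half-minimum imputation, and log transform with
#' standardization.
#'
#' @inheritParams batch_adjust
#' @inheritParams detection_filter
#' @inheritParams prune_collinear
#' @param standardize passed to [log_standardize()].
#' @return List with `matrix` (imputed [metabolite_matrix()]), `log`
#'   (standardized log matrix), `dropped_collinear`, `batch_factors`.
#' @export
prep_metabolome <- function(m, mode = "per_metabolite", max_undetected = 0.25,
                            rho_max = 0.5, absolute = FALSE,
                            standardize = TRUE) {
  adj <- batch_adjust(m, mode = mode)
  det <- detection_filter(adj, max_undetected = max_undetected)
  pr <- prune_collinear(det, rho_max = rho_max, absolute = absolute)
  imp <- half_min_impute(pr$matrix)
  list(matrix = imp, log = log_standardize(imp, standardize = standardize),
       dropped_collinear = pr$dropped,
       batch_factors = attr(adj, "batch_factors"))
}
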