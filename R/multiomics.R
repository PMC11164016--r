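#' Select taxa and metabolites for the cross-omics correlation map
#'
#' Returns the union of the top `n_taxa` genera per topic, the topics
#' ("clusters") themselves as features, and the `n_metab` metabolites with
#' the highest variance of log values, plus any pinned identifiers (e.g.
#' the stability-selected outcome metabolite) whether or not they make the
#' variance cut.
#'
#' @param topics a fitted `topic_model`.
#' @param genus_table genus-level [count_table()] supplying the candidate
#'   taxa.
#' @param metab_log matrix of log metabolite values.
#' @param n_taxa top taxa per topic (default 5).
#' @param n_metab top metabolites by variance (default 50).
#' @param pinned_taxa,pinned_metabolites ids always included; an unknown id
#'   is an error naming it.
#' @return List with `taxa`, `clusters`, `metabolites`.
#' @export
select_features <- function(topics, genus_table, metab_log, n_taxa = 5,
                            n_metab = 50, pinned_taxa = NULL,
                            pinned_metabolites = NULL) {
  taxa <- unique(unlist(top_taxa(topics, n = n_taxa)))
  genus_ids <- colnames(genus_table$counts)
  taxa <- intersect(taxa, genus_ids)
  bad_t <- setdiff(pinned_taxa, genus_ids)
  if (length(bad_t)) stopf("pinned taxa not found: %s", paste(bad_t, collapse = ", "))
  taxa <- unique(c(taxa, pinned_taxa))

  met_ids <- colnames(metab_log)
  bad_m <- setdiff(pinned_metabolites, met_ids)
  if (length(bad_m)) stopf("pinned metabolites not found: %s",
                           paste(bad_m, collapse = ", "))
  v <- apply(metab_log, 2, var)
  top <- met_ids[order(-v, met_ids)][seq_len(min(n_metab, length(met_ids)))]
  mets <- unique(c(top, pinned_metabolites))
  list(taxa = taxa, clusters = rownames(topics$topic_term), metabolites = mets)
}

#' Cross-compartment Spearman correlation map
#'
#' Spearman rho and two-sided p-value for every (row feature, column
#' feature) pair over paired samples (matched by rowname), with a
#' significance mask at `p < alpha` (unadjusted by default; an FDR mode is
#' available via `adjust`). Constant features give `NA` rho and are
#' masked.
#'
#' @param rows numeric matrix of row features (e.g. clr taxa and cluster
#'   abundances), samples in rows.
#' @param cols numeric matrix of column features (e.g. log metabolites);
#'   rownames must match `rows` (same patients).
#' @param alpha significance threshold for the mask.
#' @param adjust p-value adjustment method (`"none"` default, or any
#'   [stats::p.adjust] method such as `"BH"`).
#' @return Object of class `cross_cor_map`: list with `rho`, `p`, `mask`,
#'   `alpha`, `n`.
#' @export
cross_correlate <- function(rows, cols, alpha = 0.05, adjust = "none") {
  rows <- as.matrix(rows)
  cols <- as.matrix(cols)
  common <- intersect(rownames(rows), rownames(cols))
  dropped <- (nrow(rows) - length(common)) + (nrow(cols) - length(common))
  if (length(common) < 3) stopf("need at least 3 paired samples, have %d",
                                length(common))
  if (dropped > 0)
    message(sprintf("cross_correlate: %d unpaired sample(s) dropped; %d pairs used",
                    dropped, length(common)))
  R <- rows[common, , drop = FALSE]
  C <- cols[common, , drop = FALSE]
  rho <- matrix(NA_real_, ncol(R), ncol(C), dimnames = list(colnames(R), colnames(C)))
  pv <- rho
  for (i in seq_len(ncol(R))) {
    for (j in seq_len(ncol(C))) {
      if (sd(R[, i]) == 0 || sd(C[, j]) == 0) next
      ct <- suppressWarnings(cor.test(R[, i], C[, j], method = "spearman"))
      rho[i, j] <- unname(ct$estimate)
      pv[i, j] <- ct$p.value
    }
  }
  padj <- pv
  if (adjust != "none") padj[] <- stats::p.adjust(pv, method = adjust)
  mask <- !is.na(padj) & padj < alpha
  structure(list(rho = rho, p = pv, p_adj = padj, mask = mask, alpha = alpha,
                 n = length(common), adjust = adjust),
            class = "cross_cor_map")
}

#' @export
print.cross_cor_map <- function(x, ...) {
  cat(sprintf("cross-omics Spearman map: %d x %d features, n = %d pairs, %d significant at p < %g%s\n",
              nrow(x$rho), ncol(x$rho), x$n, sum(x$mask), x$alpha,
              if (x$adjust != "none") sprintf(" (%s-adjusted)", x$adjust) else ""))
  sig <- which(x$mask, arr.ind = TRUE)
  if (nrow(sig)) {
    v <- x$rho[x$mask]
    o <- order(v)
    lo <- sig[o[1], ]; hi <- sig[o[length(o)], ]
    cat(sprintf("  most negative: %s ~ %s (rho = %.2f)\n",
                rownames(x$rho)[lo[1]], colnames(x$rho)[lo[2]], min(v)))
    cat(sprintf("  most positive: %s ~ %s (rho = %.2f)\n",
                rownames(x$rho)[hi[1]], colnames(x$rho)[hi[2]], max(v)))
  }
  invisible(x)
}
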