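#' Filter samples by read depth
#'
#' Retains samples whose total read count is strictly greater than
#' `min_reads` (default 1000, i.e. the ">1,000 sequence reads" rule),
#' preserving sample order.
#'
#' @param t a [count_table()].
#' @param min_reads minimum total read count (exclusive).
#' @return The filtered [count_table()]. If no sample survives, an empty
#'   table is returned with a warning.
#' @export
filter_samples <- function(t, min_reads = 1000) {
  stopifnot(inherits(t, "count_table"))
  keep <- rowSums(t$counts) > min_reads
  if (!any(keep)) warnf("read-depth filter removed all %d samples", nrow(t$counts))
  subset_count_table(t, samples = which(keep))
}

#' Filter ASVs by relative abundance and prevalence
#'
#' Keeps features whose within-sample relative abundance exceeds `min_rel`
#' in at least `min_samples` samples (default: ">0.1% in at least two
#' samples"). Relative abundance is computed per sample from the table as
#' given, i.e. after any sample filtering.
#'
#' @param t a [count_table()].
#' @param min_rel relative-abundance threshold (exclusive).
#' @param min_samples minimum number of qualifying samples.
#' @return The filtered [count_table()].
#' @export
filter_asvs <- function(t, min_rel = 0.001, min_samples = 2) {
  stopifnot(inherits(t, "count_table"))
  if (nrow(t$counts) < min_samples)
    stopf("need at least %d samples, have %d", min_samples, nrow(t$counts))
  tot <- rowSums(t$counts)
  rel <- t$counts / ifelse(tot > 0, tot, 1)
  keep <- colSums(rel > min_rel) >= min_samples
  subset_count_table(t, features = which(keep))
}

# Label used for a feature when genus is unassigned: best assigned higher
# rank, e.g. "Lachnospiraceae Family".
genus_label <- function(taxonomy) {
  lab <- taxonomy$genus
  ranks <- intersect(c("family", "order", "class", "phylum", "kingdom"),
                     names(taxonomy))
  for (r in ranks) {
    fall <- is.na(lab) & !is.na(taxonomy[[r]])
    lab[fall] <- paste(taxonomy[[r]][fall],
                       paste0(toupper(substring(r, 1, 1)), substring(r, 2)))
  }
  lab[is.na(lab)] <- "Unclassified"
  lab
}

#' Collapse an ASV table to genus level
#'
#' Sums member-ASV counts per genus and retains genera present (nonzero
#' count) in at least `ceiling(prevalence_min * n_samples)` samples
#' (default: "present in at least 1% of the samples"). ASVs without a genus
#' assignment are grouped under their best assigned higher rank, e.g.
#' `"Lachnospiraceae Family"`.
#'
#' @param t a [count_table()] with taxonomy.
#' @param prevalence_min minimum fraction of samples a genus must appear in.
#' @return A genus-level [count_table()] (no taxonomy).
#' @export
collapse_to_genus <- function(t, prevalence_min = 0.01) {
  stopifnot(inherits(t, "count_table"))
  if (is.null(t$taxonomy)) stopf("collapse_to_genus requires taxonomy")
  tax <- t$taxonomy
  lab <- setNames(genus_label(tax), tax$feature_id)
  feats <- colnames(t$counts)
  if (!all(feats %in% names(lab)))
    stopf("taxonomy missing for features: %s",
          paste(head(setdiff(feats, names(lab)), 3), collapse = ", "))
  groups <- factor(lab[feats])
  # rowsum on the transposed matrix sums member ASVs per genus
  gen <- t(rowsum(t(t$counts), group = groups))
  thr <- ceiling(prevalence_min * nrow(gen))
  keep <- colSums(gen > 0) >= thr
  count_table(gen[, keep, drop = FALSE])
}

#' Select the analysis timepoint per patient
#'
#' Implements the early post-intervention rule: per patient, the 28-day
#' sample is used when present, otherwise the 10-day sample; the selected
#' row is labeled `"early_post"` in a new `timepoint_label` column. Late
#' (9-month) samples pass through labeled `"late"`. Other timepoints and
#' donors are not returned.
#'
#' @param meta sample metadata (see [validate_sample_meta()]).
#' @return The selected metadata rows with a `timepoint_label` column.
#' @export
select_analysis_sample <- function(meta) {
  pat <- meta[meta$role == "patient", , drop = FALSE]
  rows <- list()
  for (p in unique(pat$patient_id)) {
    sub <- pat[pat$patient_id == p, , drop = FALSE]
    pick <- sub[sub$timepoint == "post28", , drop = FALSE]
    if (!nrow(pick)) pick <- sub[sub$timepoint == "post10", , drop = FALSE]
    if (nrow(pick)) {
      pick$timepoint_label <- "early_post"
      rows[[length(rows) + 1L]] <- pick
    }
    late <- sub[sub$timepoint == "late", , drop = FALSE]
    if (nrow(late)) {
      late$timepoint_label <- "late"
      rows[[length(rows) + 1L]] <- late
    }
  }
  if (!length(rows)) {
    out <- pat[0, , drop = FALSE]
    out$timepoint_label <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard microbiome preprocessing chain
#'
#' Applies the read-depth filter, the ASV relative-abundance filter, and
#' genus agglomeration, in that order.
#'
#' @inheritParams filter_samples
#' @inheritParams filter_asvs
#' @inheritParams collapse_to_genus
#' @return A list with `asv` (filtered ASV table) and `genus` (collapsed
#'   genus table).
#' @export
prep_microbiome <- function(t, min_reads = 1000, min_rel = 0.001,
                            min_samples = 2, prevalence_min = 0.01) {
  t1 <- filter_samples(t, min_reads = min_reads)
  t2 <- filter_asvs(t1, min_rel = min_rel, min_samples = min_samples)
  list(asv = t2, genus = collapse_to_genus(t2, prevalence_min = prevalence_min))
}
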