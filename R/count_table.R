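#' ASV/genus count table
#'
#' Container for a samples x features matrix of nonnegative integer counts
#' (ASVs or genera) with an optional taxonomy map. Samples are rows.
#'
#' @param counts numeric matrix, samples in rows, features in columns, with
#'   unique row and column names. Values must be nonnegative integers.
#' @param taxonomy optional `data.frame` with columns `feature_id`, `genus`
#'   and optionally higher ranks (e.g. `family`). `genus` may be `NA` for
#'   unassigned features; [collapse_to_genus()] then falls back to the best
#'   assigned higher rank.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `taxonomy`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' count_table(m)
#' @export
count_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count_table requires sample (row) and feature (column) names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate feature ids")
  if (any(counts < 0) || any(is.na(counts)))
    stopf("counts must be nonnegative and non-missing")
  if (max(abs(counts - round(counts))) > 1e-8)
    stopf("counts must be integers")
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(c("feature_id", "genus") %in% names(taxonomy)))
      stopf("taxonomy needs columns 'feature_id' and 'genus'")
    extra <- setdiff(taxonomy$feature_id, colnames(counts))
    if (length(extra))
      stopf("taxonomy refers to unknown features: %s",
            paste(head(extra, 3), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total reads: %s; median depth: %s\n",
              format(sum(x$counts), big.mark = ","),
              format(median(rowSums(x$counts)), big.mark = ",")))
  if (!is.null(x$taxonomy)) {
    cat(sprintf("  taxonomy: %d features mapped to %d genera\n",
                nrow(x$taxonomy), length(unique(x$taxonomy$genus))))
  }
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

n_samples <- function(t) nrow(t$counts)
n_features <- function(t) ncol(t$counts)

#' Subset a count table by samples and/or features
#'
#' @param t a [count_table()].
#' @param samples,features row/column selectors (names, indices or logical).
#' @return The subsetted [count_table()]; taxonomy is pruned accordingly.
#' @export
subset_count_table <- function(t, samples = NULL, features = NULL) {
  counts <- t$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(features)) counts <- counts[, features, drop = FALSE]
  tax <- t$taxonomy
  if (!is.null(tax)) tax <- tax[tax$feature_id %in% colnames(counts), , drop = FALSE]
  structure(list(counts = counts, taxonomy = tax), class = "count_table")
}

#' Read / write count tables as TSV
#'
#' The TSV layout is features in rows and samples in columns (the common
#' ASV-table export), first column `feature_id`. Taxonomy is a separate TSV
#' with columns `feature_id`, `genus`, and optional higher ranks; a
#' semicolon-delimited 7-rank `lineage` column
#' (`Kingdom;Phylum;Class;Order;Family;Genus;Species`) is also accepted.
#'
#' @param path file path of the count TSV.
#' @param taxonomy_path optional taxonomy TSV path.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, taxonomy_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  feats <- as.character(df[[1]])
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- feats
  tax <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path) else NULL
  count_table(m, taxonomy = tax)
}

read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"genus" %in% names(tx) && "lineage" %in% names(tx)) {
    ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
    parts <- strsplit(tx$lineage, ";", fixed = TRUE)
    for (i in seq_along(ranks)) {
      tx[[ranks[i]]] <- vapply(parts, function(p) {
        v <- if (length(p) >= i) trimws(p[i]) else ""
        if (v == "") NA_character_ else v
      }, character(1))
    }
    tx$lineage <- NULL
  }
  tx
}

#' @param t a [count_table()].
#' @rdname read_count_table
#' @export
write_count_table <- function(t, path, taxonomy_path = NULL) {
  df <- data.frame(feature_id = colnames(t$counts),
                   t(t$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(taxonomy_path) && !is.null(t$taxonomy))
    utils::write.table(t$taxonomy, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample clinical/design annotations used throughout the
#' pipeline: `sample_id`, `patient_id`, `role` (patient/donor), `arm`
#' (FMT/placebo, `NA` for donors), `timepoint` (baseline, pre, post10,
#' post28, late), `donor_id`, `outcome` (grade II-IV aGVHD, 0/1),
#' `prophylaxis` (PTCy/other). Donors must carry `NA` arm and outcome; a
#' patient may have at most one sample per (timepoint, assay).
#'
#' @param meta a data.frame of sample metadata.
#' @return `meta`, invisibly, after validation.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "patient_id", "role", "arm", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("metadata missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample ids in metadata")
  d <- meta$role == "donor"
  if (any(!is.na(meta$arm[d]))) stopf("donor rows must have NA arm")
  if ("outcome" %in% names(meta) && any(!is.na(meta$outcome[d])))
    stopf("donor rows must have NA outcome")
  key <- paste(meta$patient_id, meta$timepoint,
               if ("assay" %in% names(meta)) meta$assay else "", sep = "\r")
  if (anyDuplicated(key[!d]))
    stopf("a patient has more than one sample at one timepoint")
  invisible(meta)
}
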