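#' Presence/absence binary similarity between ASV sets
#'
#' Default is the Jaccard index `|A n B| / |A u B|`, which ignores joint
#' absences and reads as "the fraction of shared ASVs". Dice and
#' simple-matching coefficients are available behind the `method` flag
#' (simple matching needs the ASV `universe` to count joint absences).
#'
#' @param a,b character vectors of present ASV ids.
#' @param method `"jaccard"`, `"dice"`, or `"simple_matching"`.
#' @param universe all ASV ids (required for simple matching).
#' @return Similarity in `[0, 1]`. Two empty sets return 0 with a warning
#'   (Jaccard/Dice).
#' @examples
#' binary_similarity(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
binary_similarity <- function(a, b, method = c("jaccard", "dice",
                                               "simple_matching"),
                              universe = NULL) {
  method <- match.arg(method)
  a <- unique(a); b <- unique(b)
  ni <- length(intersect(a, b))
  if (method == "simple_matching") {
    if (is.null(universe)) stopf("simple matching requires the ASV universe")
    nu <- length(unique(universe))
    return((ni + nu - length(union(a, b))) / nu)
  }
  if (length(a) == 0 && length(b) == 0) {
    warnf("both ASV sets empty; similarity set to 0")
    return(0)
  }
  if (method == "dice") return(2 * ni / (length(a) + length(b)))
  ni / length(union(a, b))
}

#' Donor-engraftment similarity analysis for one genus
#'
#' For every FMT-arm patient with an early post-intervention stool sample
#' and an assigned donor, restricts the filtered ASV table to the given
#' genus, computes the presence/absence binary similarity between the
#' patient's early post-FMT ASV set and the donor's, and correlates it
#' (Spearman) with both the post-FMT relative abundance of the genus and
#' the pre-to-post abundance change.
#'
#' @param counts filtered ASV-level [count_table()] with taxonomy.
#' @param meta sample metadata ([validate_sample_meta()]), stool samples.
#' @param genus genus to analyze (e.g. `"Faecalibacterium"`).
#' @param method similarity flavor, see [binary_similarity()].
#' @param min_count minimum read count for an ASV to count as present.
#' @return List with `records` (one row per patient: `patient_id`,
#'   `donor_id`, `similarity`, `post_abundance`, `pre_abundance`,
#'   `abundance_change`, `empty_sets` flag), `rho_abundance`/`p_abundance`
#'   (similarity vs post abundance), `rho_change`/`p_change` (vs change),
#'   and `n`.
#' @export
engraftment_analysis <- function(counts, meta, genus, method = "jaccard",
                                 min_count = 1) {
  stopifnot(inherits(counts, "count_table"))
  if (is.null(counts$taxonomy)) stopf("engraftment analysis requires taxonomy")
  tax <- counts$taxonomy
  genus_asvs <- tax$feature_id[!is.na(tax$genus) & tax$genus == genus]
  genus_asvs <- intersect(genus_asvs, colnames(counts$counts))
  if (!length(genus_asvs)) stopf("no ASVs mapped to genus '%s'", genus)

  stool <- if ("assay" %in% names(meta)) {
    meta[meta$assay == "stool", , drop = FALSE]
  } else meta
  early <- select_analysis_sample(stool)
  early <- early[early$timepoint_label == "early_post", , drop = FALSE]
  early <- early[!is.na(early$arm) & early$arm == "FMT" & !is.na(early$donor_id), ,
                 drop = FALSE]
  donors <- stool[stool$role == "donor", , drop = FALSE]
  avail <- rownames(counts$counts)
  early <- early[early$sample_id %in% avail, , drop = FALSE]
  if (!nrow(early)) stopf("no eligible FMT patients with early post samples")

  presence <- function(sid) {
    v <- counts$counts[sid, genus_asvs]
    genus_asvs[v >= min_count]
  }
  tot <- rowSums(counts$counts)
  gen_rel <- rowSums(counts$counts[, genus_asvs, drop = FALSE]) / tot

  rec <- lapply(seq_len(nrow(early)), function(i) {
    p <- early$patient_id[i]
    dsid <- donors$sample_id[donors$donor_id == early$donor_id[i]]
    dsid <- intersect(dsid, avail)
    if (!length(dsid)) return(NULL)
    a <- presence(early$sample_id[i])
    b <- presence(dsid[1])
    empty <- length(a) == 0 && length(b) == 0
    sim <- if (empty) 0 else
      binary_similarity(a, b, method = method, universe = genus_asvs)
    pre_sid <- stool$sample_id[stool$patient_id == p & stool$timepoint %in% "pre"]
    pre_sid <- intersect(pre_sid, avail)
    pre_ab <- if (length(pre_sid)) unname(gen_rel[pre_sid[1]]) else NA_real_
    data.frame(patient_id = p, donor_id = early$donor_id[i],
               similarity = sim, post_abundance = unname(gen_rel[early$sample_id[i]]),
               pre_abundance = pre_ab,
               abundance_change = unname(gen_rel[early$sample_id[i]]) - pre_ab,
               empty_sets = empty, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  if (is.null(records) || nrow(records) < 2)
    stopf("Spearman correlation undefined: fewer than two eligible patients")

  ct_ab <- suppressWarnings(cor.test(records$similarity, records$post_abundance,
                                     method = "spearman"))
  cc <- !is.na(records$abundance_change)
  ct_ch <- if (sum(cc) >= 2) {
    suppressWarnings(cor.test(records$similarity[cc], records$abundance_change[cc],
                              method = "spearman"))
  } else NULL
  list(records = records, genus = genus,
       rho_abundance = unname(ct_ab$estimate), p_abundance = ct_ab$p.value,
       rho_change = if (!is.null(ct_ch)) unname(ct_ch$estimate) else NA_real_,
       p_change = if (!is.null(ct_ch)) ct_ch$p.value else NA_real_,
       n = nrow(records))
}
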