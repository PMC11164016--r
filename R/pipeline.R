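#' Default pipeline configuration
#'
#' Nested list mirroring every stage's defaults. `simulate` holds
#' [sim_config()] arguments; `stages` toggles stages on/off; `params`
#' holds stage parameters. One global `seed` fans out to per-stage seeds
#' through a counter scheme, so disabling one stage does not shift another
#' stage's random stream.
#'
#' @param seed global RNG seed.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    out_dir = NULL,
    simulate = list(),
    stages = list(prep = TRUE, topics = TRUE, ordination = TRUE,
                  taxa_lasso = TRUE, metabolome = TRUE, metab_lasso = TRUE,
                  splsda = TRUE, engraftment = TRUE, crossmap = TRUE),
    params = list(
      min_reads = 1000, min_rel = 0.001, min_samples = 2, prevalence_min = 0.01,
      k_min = 2, k_max = 10, restarts = 5,
      n_perm = 999, n_groups = 3,
      taxa_runs = 100, taxa_folds = 4, taxa_nlambda = 30,
      metab_mode = "per_metabolite", max_undetected = 0.25, rho_max = 0.5,
      metab_repeats = 100, metab_folds = 10, metab_nlambda = 100,
      splsda_repeats = 30, splsda_folds = 4, keepX_grid = c(5, 10, 20, 50),
      max_components = 2,
      engraftment_genus = NULL,  # default: the simulation's planted genus
      n_taxa = 5, n_metab = 50, alpha = 0.05
    )
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config(seed = config$seed %||% 1)
  modifyList(base, config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full multi-omics analysis pipeline
#'
#' Executes the enabled stages in dependency order on a simulated trial:
#' simulate, microbiome prep, topic modeling with k selection, ordination
#' and permutation tests on cluster abundances, zero-sum taxa lasso with
#' stability selection, metabolome prep, metabolite stability lasso,
#' sPLS-DA, donor-engraftment analysis, and the cross-omics correlation
#' map. Returns (and optionally writes) a machine-readable report of the
#' headline statistics of every stage.
#'
#' @param config a configuration list (see [default_pipeline_config()]),
#'   or the path of a YAML file with the same structure.
#' @param out_dir optional output directory; when given, stage artifacts
#'   (TSVs) and `report.json` are written there.
#' @return The report, an S3 list of class `fmtomics_report`, invisibly
#'   when writing.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  cfg <- read_pipeline_config(if (is.list(config) || is.character(config))
    config else stopf("config must be a list or a YAML path"))
  p <- cfg$params
  st <- cfg$stages
  out_dir <- out_dir %||% cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed)

  # --- simulate -------------------------------------------------------------
  sim_args <- modifyList(list(seed = stage_seed(cfg$seed, 10)), cfg$simulate)
  sim <- run_stage("simulate", simulate_trial(do.call(sim_config, sim_args)))
  planted_genus <- sim$config$planted_genus
  report$simulate <- list(
    n_patients = sim$config$n_patients,
    n_fmt = sum(sim$meta$arm[!duplicated(sim$meta$patient_id)] == "FMT", na.rm = TRUE),
    n_stool_samples = sum(sim$meta$assay == "stool"),
    n_serum_samples = sum(sim$meta$assay == "serum"),
    event_rate = mean(sim$outcomes$outcome))

  # --- microbiome prep ------------------------------------------------------
  if (!st$prep) {
    return(finish_report(report, out_dir))
  }
  prep <- run_stage("prep", prep_microbiome(
    sim$counts, min_reads = p$min_reads, min_rel = p$min_rel,
    min_samples = p$min_samples, prevalence_min = p$prevalence_min))
  meta_stool <- sim$meta[sim$meta$assay == "stool" &
                           sim$meta$sample_id %in% rownames(prep$asv$counts), ]
  early <- select_analysis_sample(meta_stool)
  early <- early[early$timepoint_label == "early_post", ]
  report$prep <- list(
    n_samples = nrow(prep$asv$counts), n_asvs = ncol(prep$asv$counts),
    n_genera = ncol(prep$genus$counts), n_early_post = nrow(early))

  # --- topic model ----------------------------------------------------------
  if (st$topics) {
    sel <- run_stage("topics", select_k(
      prep$genus, k_min = p$k_min, k_max = p$k_max,
      seed = stage_seed(cfg$seed, 20), restarts = p$restarts))
    tm <- sel$models[[as.character(sel$k_star)]]
    report$topics <- list(k_star = sel$k_star,
                          cao = setNames(sel$scores$cao, sel$scores$k),
                          top_taxa = top_taxa(tm, n = min(5, ncol(tm$topic_term))),
                          converged = tm$converged)
  }

  # --- ordination & group tests on cluster abundances -----------------------
  if (st$ordination && st$topics) {
    report$ordination <- run_stage("ordination", {
      theta <- cluster_abundances(tm)
      th_early <- theta[intersect(rownames(theta), early$sample_id), , drop = FALSE]
      em <- early[match(rownames(th_early), early$sample_id), ]
      d <- aitchison_distance(clr_transform(th_early, pseudocount = 1e-6))
      pa <- permanova(d, em$arm, n_perm = p$n_perm,
                      seed = stage_seed(cfg$seed, 30))
      has_out <- !is.na(em$outcome)
      po <- if (sum(has_out) >= 4 && length(unique(em$outcome[has_out])) == 2) {
        permanova(as.dist(as.matrix(d)[has_out, has_out]), em$outcome[has_out],
                  n_perm = p$n_perm, seed = stage_seed(cfg$seed, 31))
      } else NULL
      wil <- lapply(seq_len(ncol(th_early)), function(j)
        group_compare(th_early[, j], em$arm, correction = "bonferroni",
                      m = ncol(th_early))$p_adj)
      names(wil) <- colnames(th_early)
      groups <- ward_groups(theta, n_groups = p$n_groups, scale = "column")
      list(permanova_arm = list(pseudo_F = pa$pseudo_F, r2 = pa$r2,
                                p = pa$p_value),
           permanova_outcome = if (!is.null(po))
             list(pseudo_F = po$pseudo_F, r2 = po$r2, p = po$p_value),
           wilcoxon_arm_bonferroni = wil,
           sample_groups = as.list(table(groups)))
    })
  }

  # --- taxa-level zero-sum lasso -------------------------------------------
  if (st$taxa_lasso) {
    report$taxa_lasso <- run_stage("taxa_lasso", {
      gsub_tab <- subset_count_table(prep$genus, samples = early$sample_id)
      out <- sim$outcomes$outcome[match(early$patient_id, sim$outcomes$patient_id)]
      keep <- !is.na(out)
      X <- logratio_features(subset_count_table(gsub_tab, samples = which(keep)))
      stab <- stability_select(X, out[keep], n_runs = p$taxa_runs,
                               n_folds = p$taxa_folds, nlambda = p$taxa_nlambda,
                               seed = stage_seed(cfg$seed, 40))
      if (!is.null(out_dir))
        utils::write.table(stab, file.path(out_dir, "taxa_stability.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      pl <- stab[stab$feature == planted_genus, ]
      list(n_patients = sum(keep),
           top_features = head(stab[, c("feature", "selection_probability",
                                        "mean_coefficient", "sign")], 10),
           planted_genus = planted_genus,
           planted_probability = if (nrow(pl)) pl$selection_probability else NA,
           planted_sign = if (nrow(pl)) pl$sign else NA)
    })
  }

  # --- metabolome prep ------------------------------------------------------
  if (st$metabolome) {
    metab <- run_stage("metabolome", prep_metabolome(
      sim$metab, mode = p$metab_mode, max_undetected = p$max_undetected,
      rho_max = p$rho_max))
    report$metabolome <- list(
      n_input = ncol(sim$metab$intensities),
      n_detected = ncol(sim$metab$intensities) -
        sum(colMeans(sim$metab$intensities == 0) > p$max_undetected),
      n_retained = ncol(metab$matrix$intensities),
      n_dropped_collinear = length(metab$dropped_collinear))
    pca <- pca_scores(metab$log, k = 2)
    report$metabolome$pca_explained <- pca$explained
  }

  # metabolite-level models use early post serum samples of patients with
  # a known outcome; anchor reruns are excluded (duplicate identities)
  if ((st$metab_lasso || st$splsda || st$crossmap) && st$metabolome) {
    serum <- sim$meta[sim$meta$assay == "serum" & sim$meta$timepoint == "post28", ]
    rerun_ids <- sim$metab$anchor_pairs$target
    ids <- intersect(setdiff(rownames(metab$log), rerun_ids), serum$sample_id)
    serum <- serum[match(ids, serum$sample_id), ]
    y_met <- sim$outcomes$outcome[match(serum$patient_id, sim$outcomes$patient_id)]
    keep <- !is.na(y_met)
    Xmet <- metab$log[ids[keep], , drop = FALSE]
    y_met <- y_met[keep]
    ptcy <- as.integer(serum$prophylaxis[keep] == "PTCy")
    serum_patients <- serum$patient_id[keep]
  }

  # --- metabolite stability lasso ------------------------------------------
  if (st$metab_lasso && st$metabolome) {
    report$metab_lasso <- run_stage("metab_lasso", {
      stab <- logistic_lasso_stability(Xmet, y_met, covariate = ptcy,
                                       n_folds = p$metab_folds,
                                       n_repeats = p$metab_repeats,
                                       nlambda = p$metab_nlambda,
                                       seed = stage_seed(cfg$seed, 50))
      if (!is.null(out_dir))
        utils::write.table(stab, file.path(out_dir, "metabolite_stability.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      planted <- sim$truth$planted_metabolite
      pl <- stab[stab$feature == planted, ]
      list(n_samples = nrow(Xmet), n_runs = stab$n_runs[1],
           top_features = head(stab[, c("feature", "selection_probability",
                                        "mean_coefficient", "sign")], 5),
           planted_metabolite = planted,
           planted_runs_selected = if (nrow(pl))
             round(pl$selection_probability * pl$n_runs) else NA,
           planted_sign = if (nrow(pl)) pl$sign else NA,
           covariate_coef = attr(stab, "covariate_coef"))
    })
  }

  # --- sPLS-DA --------------------------------------------------------------
  if (st$splsda && st$metabolome) {
    report$splsda <- run_stage("splsda", {
      fit <- splsda(Xmet, y_met, max_components = p$max_components,
                    keepX_grid = p$keepX_grid, n_folds = p$splsda_folds,
                    n_repeats = p$splsda_repeats,
                    seed = stage_seed(cfg$seed, 60))
      top <- order(-abs(fit$loadings[, 1]))[1:5]
      list(ncomp = fit$ncomp, keepX = fit$keepX, ber = fit$ber,
           ber_sd = fit$ber_sd,
           top_loadings = setNames(fit$loadings[top, 1],
                                   rownames(fit$loadings)[top]))
    })
  }

  # --- engraftment ----------------------------------------------------------
  if (st$engraftment) {
    report$engraftment <- run_stage("engraftment", {
      gen <- p$engraftment_genus %||% planted_genus
      ea <- engraftment_analysis(prep$asv, meta_stool, genus = gen)
      if (!is.null(out_dir))
        utils::write.table(ea$records, file.path(out_dir, "engraftment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(genus = gen, n = ea$n, rho_abundance = ea$rho_abundance,
           p_abundance = ea$p_abundance, rho_change = ea$rho_change,
           p_change = ea$p_change)
    })
  }

  # --- cross-omics map ------------------------------------------------------
  if (st$crossmap && st$topics && st$metabolome) {
    report$crossmap <- run_stage("crossmap", {
      feats <- select_features(tm, prep$genus, metab$log, n_taxa = p$n_taxa,
                               n_metab = p$n_metab,
                               pinned_metabolites = intersect(
                                 sim$truth$planted_metabolite, colnames(metab$log)))
      gtab <- subset_count_table(prep$genus, samples = early$sample_id)
      gclr <- clr_transform(gtab)[, feats$taxa, drop = FALSE]
      theta_e <- cluster_abundances(tm)
      theta_e <- theta_e[intersect(rownames(theta_e), early$sample_id), , drop = FALSE]
      rows <- cbind(gclr[rownames(theta_e), , drop = FALSE], theta_e)
      rownames(rows) <- early$patient_id[match(rownames(rows), early$sample_id)]
      cols <- Xmet[, feats$metabolites, drop = FALSE]
      rownames(cols) <- serum_patients
      cm <- cross_correlate(rows, cols, alpha = p$alpha)
      sig <- which(cm$mask, arr.ind = TRUE)
      extremes <- if (nrow(sig)) {
        v <- cm$rho[cm$mask]
        list(min_rho = min(v), max_rho = max(v), n_significant = sum(cm$mask))
      } else list(min_rho = NA, max_rho = NA, n_significant = 0L)
      c(list(n_row_features = ncol(rows), n_metabolites = ncol(cols),
             n_pairs = cm$n), extremes)
    })
  }

  finish_report(report, out_dir)
}

finish_report <- function(report, out_dir) {
  class(report) <- "fmtomics_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(report))
  }
  report
}

#' @export
print.fmtomics_report <- function(x, ...) {
  cat("fmtomics pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$topics)) cat("  topics: k* =", x$topics$k_star, "\n")
  if (!is.null(x$ordination))
    cat("  PERMANOVA FMT vs placebo: p =", x$ordination$permanova_arm$p, "\n")
  if (!is.null(x$taxa_lasso))
    cat(sprintf("  taxa lasso: %s selected in %.0f%% of runs (sign %s)\n",
                x$taxa_lasso$planted_genus,
                100 * x$taxa_lasso$planted_probability, x$taxa_lasso$planted_sign))
  if (!is.null(x$metab_lasso))
    cat(sprintf("  metabolite lasso: %s selected in %d/%d runs (sign %s)\n",
                x$metab_lasso$planted_metabolite,
                x$metab_lasso$planted_runs_selected,
                x$metab_lasso$n_runs,
                x$metab_lasso$planted_sign))
  if (!is.null(x$engraftment))
    cat(sprintf("  engraftment: rho = %.3f (n = %d)\n",
                x$engraftment$rho_abundance, x$engraftment$n))
  invisible(x)
}
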