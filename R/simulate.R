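#' Configuration for the synthetic FMT-trial generator
#'
#' Builds the configuration object consumed by [simulate_cohort()],
#' [simulate_microbiome()], [simulate_outcomes()], [simulate_metabolome()]
#' and [simulate_trial()]. Defaults emulate a 74-patient randomized 2:1
#' FMT:placebo allo-HCT trial with 4 stool donors, longitudinal stool and
#' serum sampling, three latent microbial subcommunities, a donor-ASV
#' engraftment process for the planted genus, a binary grade II-IV aGVHD
#' outcome driven by that genus, and a two-batch untargeted metabolome with
#' 18 anchor samples.
#'
#' @param n_patients number of randomized patients.
#' @param arm_ratio integer vector `c(FMT, placebo)` allocation ratio.
#' @param n_donors number of stool donors; FMT patients are assigned one.
#' @param timepoints ordered stool timepoint labels.
#' @param retention named per-timepoint probability that a patient's stool
#'   sample at that timepoint exists (missing completely at random).
#' @param serum_retention same for serum timepoints.
#' @param n_genera,n_unassigned_genera number of genera; the last
#'   `n_unassigned_genera` of them carry no genus-level taxonomy and only a
#'   family label (exercises the genus-collapse fallback).
#' @param n_asvs_per_genus integer range (min, max) of ASVs per genus.
#' @param n_topics_true number of latent subcommunities (topics).
#' @param topic_anchor_genera list (one element per topic) of anchor genus
#'   names; anchors receive high within-topic probability.
#' @param planted_genus outcome-driving genus; must be an anchor of exactly
#'   one topic.
#' @param beta_outcome log-odds of grade II-IV aGVHD per unit clr abundance
#'   of the planted genus at the early post-intervention timepoint.
#' @param gamma_prophylaxis log-odds effect of PTCy-based prophylaxis.
#' @param target_event_rate marginal outcome rate the intercept is
#'   calibrated to.
#' @param engraftment_rate probability that each donor-private ASV of the
#'   planted genus establishes in a recipient after FMT.
#' @param engraft_abundance_boost added relative abundance of the planted
#'   genus per established donor ASV (couples abundance with ASV sharing).
#' @param depth_range sequencing depth range; depths are log-uniform.
#' @param frac_low_depth fraction of stool samples re-drawn at shallow
#'   depth (200-1000 reads) to exercise the read-count filter.
#' @param n_metabolites,n_anchor_samples,frac_collinear,zero_rate,
#'   batch_scale_range,protective_beta,anchor_noise_sd serum metabolome
#'   parameters: panel size; anchor samples rerun in both batches; fraction
#'   of metabolites in correlated blocks; mean per-metabolite non-detection
#'   probability (per-metabolite rates are uniform on `[0, 2*zero_rate]`,
#'   applied as left-censoring); multiplicative per-metabolite batch factor
#'   range; conditional shift (log units) of the planted protective
#'   metabolite in patients who develop aGVHD (negative = protective); log
#'   measurement noise of anchor reruns.
#' @param p_ptcy named probabilities of PTCy-based prophylaxis per arm
#'   (deliberately imbalanced, motivating the model covariate).
#' @param seed RNG seed; all generators derive per-stage streams from it.
#' @return A classed list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 74,
                       arm_ratio = c(2, 1),
                       n_donors = 4,
                       timepoints = c("baseline", "pre", "post10", "post28", "late"),
                       retention = c(baseline = 0.96, pre = 0.80, post10 = 0.30,
                                     post28 = 0.68, late = 0.49),
                       serum_retention = c(baseline = 0.84, pre = 0.80,
                                           post28 = 0.72, late = 0.38),
                       n_genera = 60,
                       n_unassigned_genera = 2,
                       n_asvs_per_genus = c(2, 6),
                       n_topics_true = 3,
                       topic_anchor_genera = NULL,
                       planted_genus = "Faecalibacterium",
                       beta_outcome = 1.5,
                       gamma_prophylaxis = 0.5,
                       target_event_rate = 0.35,
                       engraftment_rate = 0.5,
                       engraft_abundance_boost = 0.035,
                       depth_range = c(5000, 50000),
                       frac_low_depth = 0.03,
                       n_metabolites = 250,
                       n_anchor_samples = 18,
                       frac_collinear = 0.3,
                       zero_rate = 0.15,
                       batch_scale_range = c(0.5, 2),
                       protective_beta = -1.5,
                       anchor_noise_sd = 0.05,
                       p_ptcy = c(FMT = 0.45, placebo = 0.76),
                       seed = 1) {
  if (is.null(topic_anchor_genera)) {
    topic_anchor_genera <- list(
      c("Faecalibacterium", "Alistipes", "Blautia", "Subdoligranulum", "Collinsella"),
      c("Bacteroides", "Parabacteroides", "Prevotella", "Akkermansia", "Roseburia"),
      c("Streptococcus", "Veillonella", "Escherichia-Shigella", "Lachnoclostridium",
        "Enterococcus")
    )
  }
  cfg <- list(n_patients = n_patients, arm_ratio = arm_ratio, n_donors = n_donors,
              timepoints = timepoints, retention = retention,
              serum_retention = serum_retention, n_genera = n_genera,
              n_unassigned_genera = n_unassigned_genera,
              n_asvs_per_genus = n_asvs_per_genus,
              n_topics_true = n_topics_true,
              topic_anchor_genera = topic_anchor_genera,
              planted_genus = planted_genus, beta_outcome = beta_outcome,
              gamma_prophylaxis = gamma_prophylaxis,
              target_event_rate = target_event_rate,
              engraftment_rate = engraftment_rate,
              engraft_abundance_boost = engraft_abundance_boost,
              depth_range = depth_range, frac_low_depth = frac_low_depth,
              n_metabolites = n_metabolites, n_anchor_samples = n_anchor_samples,
              frac_collinear = frac_collinear, zero_rate = zero_rate,
              batch_scale_range = batch_scale_range,
              protective_beta = protective_beta,
              anchor_noise_sd = anchor_noise_sd,
              p_ptcy = p_ptcy, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1) stopf("n_patients must be positive")
  if (length(cfg$arm_ratio) != 2 || any(cfg$arm_ratio <= 0))
    stopf("arm_ratio must be two positive numbers (FMT:placebo)")
  if (cfg$n_donors < 1) stopf("n_donors must be positive")
  n_anchor_topics <- sum(vapply(cfg$topic_anchor_genera,
                                function(a) cfg$planted_genus %in% a, logical(1)))
  if (n_anchor_topics != 1)
    stopf("planted_genus '%s' must anchor exactly one topic (anchors %d)",
          cfg$planted_genus, n_anchor_topics)
  probs <- c(cfg$retention, cfg$serum_retention, cfg$engraftment_rate,
             cfg$target_event_rate, cfg$zero_rate, cfg$frac_collinear,
             cfg$frac_low_depth, cfg$p_ptcy)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  n_anchors <- length(unique(unlist(cfg$topic_anchor_genera)))
  if (cfg$n_genera < n_anchors + cfg$n_unassigned_genera)
    stopf("n_genera too small for anchor and unassigned genera")
  invisible(cfg)
}

genus_names <- function(cfg) {
  anchors <- unique(unlist(cfg$topic_anchor_genera))
  n_fill <- cfg$n_genera - length(anchors)
  fill <- sprintf("Genus_%03d", seq_len(n_fill))
  c(anchors, fill)
}

# Genera whose ASVs carry no genus-level assignment (family label only).
unassigned_genera <- function(cfg) {
  g <- genus_names(cfg)
  if (cfg$n_unassigned_genera == 0) return(character(0))
  utils::tail(g, cfg$n_unassigned_genera)
}

#' Generate the trial cohort metadata
#'
#' Randomizes `n_patients` in the configured ratio to FMT or placebo,
#' assigns each FMT patient one of the donors, draws a PTCy-based vs other
#' prophylaxis label with per-arm probabilities, and emits one metadata row
#' per existing (patient, timepoint) stool sample, per serum sample, and
#' per donor stool sample. Per-timepoint missingness is completely at
#' random with the configured retention probabilities.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` of sample metadata (see [validate_sample_meta()]),
#'   with an `assay` column distinguishing stool from serum.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, 1), {
    n <- config$n_patients
    n_fmt <- round(n * config$arm_ratio[1] / sum(config$arm_ratio))
    if (n_fmt < 1 || n_fmt >= n && n > 1)
      n_fmt <- max(1, min(n - 1, n_fmt))
    pid <- sprintf("P%03d", seq_len(n))
    arm <- rep("placebo", n)
    arm[sample.int(n, n_fmt)] <- "FMT"
    donor_pool <- sprintf("D%d", seq_len(config$n_donors))
    donor <- rep(NA_character_, n)
    donor[arm == "FMT"] <- sample(rep_len(donor_pool, n_fmt))
    ptcy <- ifelse(runif(n) < config$p_ptcy[arm], "PTCy", "other")

    rows <- list()
    for (tp in config$timepoints) {
      keep <- runif(n) < config$retention[[tp]]
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(pid[keep], "_", tp),
          patient_id = pid[keep], role = "patient", arm = arm[keep],
          timepoint = tp, donor_id = donor[keep], prophylaxis = ptcy[keep],
          assay = "stool", stringsAsFactors = FALSE)
      }
    }
    for (tp in names(config$serum_retention)) {
      keep <- runif(n) < config$serum_retention[[tp]]
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(pid[keep], "_", tp, "_serum"),
          patient_id = pid[keep], role = "patient", arm = arm[keep],
          timepoint = tp, donor_id = donor[keep], prophylaxis = ptcy[keep],
          assay = "serum", stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(donor_pool, "_stool"),
      patient_id = donor_pool, role = "donor", arm = NA_character_,
      timepoint = NA_character_, donor_id = donor_pool,
      prophylaxis = NA_character_, assay = "stool", stringsAsFactors = FALSE)
    meta <- do.call(rbind, rows)
    meta$outcome <- NA_integer_
    rownames(meta) <- NULL
    validate_sample_meta(meta)
    meta
  })
}

# Latent structure shared by microbiome generation: true topic-term matrix,
# ASV registry, and the planted genus's donor/patient ASV pools.
build_microbiome_truth <- function(meta, config) {
  k <- config$n_topics_true
  genera <- genus_names(config)
  G <- length(genera)

  # topic-term rows: anchors get high Dirichlet mass, fillers low
  topic_term <- matrix(0, k, G, dimnames = list(paste0("topic", 1:k), genera))
  for (t in seq_len(k)) {
    a <- rep(0.25, G)
    a[match(config$topic_anchor_genera[[t]], genera)] <- 40
    topic_term[t, ] <- rdirichlet(1, a)
  }

  # ASV registry; planted genus has donor-private + cosmopolitan ASVs
  n_asv <- sample(config$n_asvs_per_genus[1]:config$n_asvs_per_genus[2],
                  G, replace = TRUE)
  planted_i <- match(config$planted_genus, genera)
  n_private <- 12L; n_common <- 12L
  n_asv[planted_i] <- config$n_donors * n_private + n_common
  asv_genus <- rep(genera, n_asv)
  asv_id <- sprintf("ASV%04d", seq_along(asv_genus))
  planted_asvs <- asv_id[asv_genus == config$planted_genus]
  private_sets <- split(planted_asvs[seq_len(config$n_donors * n_private)],
                        rep(seq_len(config$n_donors), each = n_private))
  names(private_sets) <- sprintf("D%d", seq_len(config$n_donors))
  common_pool <- utils::tail(planted_asvs, n_common)

  donor_ids <- sprintf("D%d", seq_len(config$n_donors))
  donor_sets <- lapply(donor_ids, function(d)
    c(private_sets[[d]], sample(common_pool, 2)))
  names(donor_sets) <- donor_ids

  # recipients retain only a small residual planted-genus community of
  # cosmopolitan ASVs (heavy pre-transplant loss of the genus)
  patients <- unique(meta$patient_id[meta$role == "patient"])
  own_sets <- lapply(patients, function(p) sample(common_pool, 2))
  names(own_sets) <- patients

  families <- c("Lachnospiraceae", "Ruminococcaceae", "Oscillospiraceae",
                "Bacteroidaceae", "Erysipelotrichaceae")
  unassigned <- unassigned_genera(config)
  taxonomy <- data.frame(
    feature_id = asv_id,
    genus = ifelse(asv_genus %in% unassigned, NA_character_, asv_genus),
    family = sample(families, length(asv_id), replace = TRUE),
    stringsAsFactors = FALSE)
  # all ASVs of one unassigned genus share one family so they collapse together
  for (i in seq_along(unassigned)) {
    taxonomy$family[asv_genus == unassigned[i]] <-
      families[(i - 1L) %% length(families) + 1L]
  }

  list(genera = genera, topic_term = topic_term, asv_id = asv_id,
       asv_genus = asv_genus, planted_genus = config$planted_genus,
       donor_sets = donor_sets, own_sets = own_sets,
       private_sets = private_sets, common_pool = common_pool,
       taxonomy = taxonomy)
}

# Dirichlet prior over topic weights for one sample, by design cell.
topic_prior <- function(role, arm, timepoint, k) {
  base <- rep(2, k)
  if (k < 3) return(base)
  pr <- base
  if (role == "donor") pr <- c(20, 2, 0.5)
  else if (is.na(timepoint)) pr <- base
  else if (timepoint == "baseline") pr <- c(4, 3, 3)
  else if (timepoint == "pre") pr <- c(1, 2, 6)
  else if (timepoint %in% c("post10", "post28"))
    pr <- if (!is.na(arm) && arm == "FMT") c(12, 2, 1) else c(1.5, 2.5, 4)
  else if (timepoint == "late")
    pr <- if (!is.na(arm) && arm == "FMT") c(6, 2, 1) else c(3, 2.5, 2)
  if (k > 3) pr <- c(pr, rep(1, k - 3))
  pr[seq_len(k)]
}

#' Generate ASV-level stool microbiome counts
#'
#' Draws each stool sample's genus composition from a mixture of
#' `n_topics_true` Dirichlet topic distributions whose weights depend on
#' role, arm and timepoint (donors and post-FMT samples weight topic 1 up;
#' pre-dose samples weight topic 3 up), allocates genus mass to ASVs, and
#' draws multinomial counts at a log-uniform sequencing depth. Post-FMT
#' samples additionally gain the assigned donor's private ASVs of the
#' planted genus with probability `engraftment_rate`; each established ASV
#' adds `engraft_abundance_boost` relative abundance to the planted genus,
#' so donor-ASV sharing and planted-genus abundance are positively coupled.
#'
#' @param meta cohort metadata from [simulate_cohort()].
#' @param config the [sim_config()] used to build `meta`.
#' @return A list with elements `counts` (an ASV-level [count_table()] with
#'   taxonomy) and `truth` (ground-truth list: `true_topic_term`,
#'   `true_sample_topics`, `donor_asv_sets`, `engrafted_sets`, ...).
#' @export
simulate_microbiome <- function(meta, config) {
  validate_sample_meta(meta)
  stool <- meta[meta$assay == "stool", , drop = FALSE]
  if (!nrow(stool)) stopf("metadata contains no stool samples")
  with_seed(stage_seed(config$seed, 2), {
    tr <- build_microbiome_truth(stool, config)
    k <- config$n_topics_true
    G <- length(tr$genera)
    n <- nrow(stool)

    theta <- matrix(0, n, k, dimnames = list(stool$sample_id, rownames(tr$topic_term)))
    for (i in seq_len(n)) {
      theta[i, ] <- rdirichlet(1, topic_prior(stool$role[i], stool$arm[i],
                                              stool$timepoint[i], k))
    }
    comp <- theta %*% tr$topic_term  # n x G genus composition

    post_tps <- c("post10", "post28", "late")
    is_post_fmt <- stool$role == "patient" & !is.na(stool$arm) &
      stool$arm == "FMT" & stool$timepoint %in% post_tps

    # engraftment: drawn once per FMT patient, persists across post timepoints
    fmt_patients <- unique(stool$patient_id[is_post_fmt])
    engrafted <- lapply(fmt_patients, function(p) {
      d <- stool$donor_id[match(p, stool$patient_id)]
      das <- tr$donor_sets[[d]]
      das[runif(length(das)) < config$engraftment_rate]
    })
    names(engrafted) <- fmt_patients

    planted_i <- match(config$planted_genus, tr$genera)
    for (i in which(is_post_fmt)) {
      nb <- length(engrafted[[stool$patient_id[i]]])
      if (nb > 0) {
        comp[i, planted_i] <- comp[i, planted_i] + nb * config$engraft_abundance_boost
        comp[i, ] <- comp[i, ] / sum(comp[i, ])
      }
    }

    # sequencing depth: log-uniform, with a configured shallow fraction
    depth <- round(exp(runif(n, log(config$depth_range[1]), log(config$depth_range[2]))))
    shallow <- runif(n) < config$frac_low_depth
    depth[shallow] <- sample(200:1000, sum(shallow), replace = TRUE)

    # allocate genus mass to ASVs, then one multinomial draw per sample
    counts <- matrix(0, n, length(tr$asv_id),
                     dimnames = list(stool$sample_id, tr$asv_id))
    planted_cols <- which(tr$asv_genus == config$planted_genus)
    for (i in seq_len(n)) {
      w <- numeric(length(tr$asv_id))
      for (g in seq_len(G)) {
        cols <- which(tr$asv_genus == tr$genera[g])
        if (g == planted_i) {
          present <- if (stool$role[i] == "donor") {
            tr$donor_sets[[stool$patient_id[i]]]
          } else {
            own <- tr$own_sets[[stool$patient_id[i]]]
            if (is_post_fmt[i]) c(own, engrafted[[stool$patient_id[i]]]) else own
          }
          cols <- cols[tr$asv_id[cols] %in% present]
        }
        if (length(cols)) {
          w[cols] <- comp[i, g] * as.numeric(rdirichlet(1, rep(5, length(cols))))
        }
      }
      counts[i, ] <- rmultinom(1, depth[i], w / sum(w))
    }

    truth <- list(true_topic_term = tr$topic_term, true_sample_topics = theta,
                  genera = tr$genera, planted_genus = config$planted_genus,
                  donor_asv_sets = tr$donor_sets,
                  donor_private_sets = tr$private_sets,
                  common_pool = tr$common_pool, engrafted_sets = engrafted,
                  patient_asv_sets = tr$own_sets, depth = depth)
    list(counts = count_table(counts, taxonomy = tr$taxonomy), truth = truth)
  })
}

# clr value of the planted genus per patient at the early post timepoint.
planted_clr <- function(meta, counts, config) {
  stool <- meta[meta$assay == "stool" & meta$role == "patient", , drop = FALSE]
  early <- select_analysis_sample(stool)
  early <- early[early$timepoint_label == "early_post", , drop = FALSE]
  genus_tab <- collapse_to_genus(counts, prevalence_min = 0)
  m <- clr_transform(subset_count_table(genus_tab, samples = early$sample_id))
  gcol <- match(config$planted_genus, colnames(m))
  if (is.na(gcol)) stopf("planted genus '%s' absent from genus table", config$planted_genus)
  data.frame(patient_id = early$patient_id, clr_planted = m[, gcol],
             stringsAsFactors = FALSE)
}

#' Generate binary aGVHD outcomes
#'
#' Draws each patient's grade II-IV aGVHD indicator from
#' `Bernoulli(plogis(alpha + beta_outcome * clr(planted genus) +
#' gamma_prophylaxis * PTCy))`, where the clr abundance is taken at the
#' early post-intervention stool sample (post28, else post10). The
#' intercept `alpha` is calibrated by root finding so the expected marginal
#' event rate equals `target_event_rate`. Patients without an early
#' post-intervention sample get `NA`.
#'
#' @inheritParams simulate_microbiome
#' @param counts the ASV [count_table()] from [simulate_microbiome()].
#' @return A `data.frame` with `patient_id`, `outcome`, `clr_planted`,
#'   `alpha` (attribute-like column-free scalar stored as attribute).
#' @export
simulate_outcomes <- function(meta, counts, config) {
  with_seed(stage_seed(config$seed, 3), {
    df <- planted_clr(meta, counts, config)
    pat <- meta[meta$role == "patient" & !duplicated(meta$patient_id), ]
    df$ptcy <- as.integer(pat$prophylaxis[match(df$patient_id, pat$patient_id)] == "PTCy")
    eta0 <- config$beta_outcome * df$clr_planted + config$gamma_prophylaxis * df$ptcy
    alpha <- calibrate_intercept(eta0, config$target_event_rate)
    p <- plogis(alpha + eta0)
    df$outcome <- rbinom(nrow(df), 1, p)
    attr(df, "alpha") <- alpha
    df
  })
}

# Solve mean(plogis(alpha + eta0)) = target for the intercept.
calibrate_intercept <- function(eta0, target) {
  f <- function(a) mean(plogis(a + eta0)) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Generate the two-batch serum metabolome
#'
#' Log-normal metabolite intensities for every serum sample: correlated
#' blocks share a latent factor; non-detections are injected by
#' left-censoring at per-metabolite rates; samples are split into a
#' reference and a target batch and target values are scaled by
#' per-metabolite batch factors; `n_anchor_samples` reference-batch samples
#' are re-run in the target batch as anchor pairs; the planted protective
#' metabolite is shifted by `protective_beta` log units in patients who
#' develop aGVHD (early post-intervention samples).
#'
#' @inheritParams simulate_microbiome
#' @param outcomes outcome `data.frame` from [simulate_outcomes()].
#' @return A list with elements `metab` (a [metabolite_matrix()]) and
#'   `truth` (planted metabolite id, batch factors, collinear block map).
#' @export
simulate_metabolome <- function(meta, outcomes, config) {
  serum <- meta[meta$assay == "serum", , drop = FALSE]
  if (!nrow(serum)) stopf("metadata contains no serum samples")
  if (config$n_anchor_samples > nrow(serum))
    stopf("n_anchor_samples (%d) exceeds available serum samples (%d)",
          config$n_anchor_samples, nrow(serum))
  with_seed(stage_seed(config$seed, 4), {
    M <- config$n_metabolites
    n <- nrow(serum)
    met_id <- sprintf("MET%04d", seq_len(M))
    mu <- rnorm(M, 14, 1.5)
    sdv <- runif(M, 0.4, 1.2)

    # collinear blocks of ~5 sharing a latent factor (|loading| 0.85)
    n_coll <- round(config$frac_collinear * M)
    block <- rep(NA_integer_, M)
    if (n_coll >= 2) {
      sizes <- rep(5, n_coll %/% 5)
      if (n_coll %% 5 >= 2) sizes <- c(sizes, n_coll %% 5)
      block[seq_len(sum(sizes))] <- rep(seq_along(sizes), sizes)
    }
    loglevel <- matrix(rnorm(n * M), n, M)
    for (b in unique(block[!is.na(block)])) {
      idx <- which(block == b)
      z <- rnorm(n)
      loglevel[, idx] <- 0.85 * z + sqrt(1 - 0.85^2) * loglevel[, idx]
    }
    # mild timepoint shift for a third of metabolites (baseline vs later),
    # emulating the treatment-phase metabolome shift
    tp_shift <- rnorm(M, 0, 0.8) * (runif(M) < 1 / 3)
    is_base <- serum$timepoint == "baseline"
    loglevel <- sweep(loglevel, 2, sdv, `*`) + matrix(mu, n, M, byrow = TRUE) +
      outer(as.numeric(!is_base), tp_shift)

    # planted protective metabolite: shifted down in future aGVHD cases at
    # the early post-intervention timepoint
    planted_j <- which(is.na(block))[1]
    planted_id <- met_id[planted_j]
    out <- outcomes$outcome[match(serum$patient_id, outcomes$patient_id)]
    early_case <- serum$timepoint == "post28" & !is.na(out) & out == 1
    loglevel[early_case, planted_j] <- loglevel[early_case, planted_j] +
      config$protective_beta * sdv[planted_j]

    intens <- exp(loglevel)

    # non-detections: left-censoring at per-metabolite rates U(0, 2*zero_rate)
    zr <- runif(M, 0, 2 * config$zero_rate)
    zr[planted_j] <- 0
    for (j in seq_len(M)) {
      if (zr[j] > 0) {
        cut <- quantile(intens[, j], zr[j])
        intens[intens[, j] <= cut, j] <- 0
      }
    }

    # batch split + anchors rerun in the target batch
    n_ref <- ceiling(0.55 * n)
    batch <- rep(c("reference", "target"), c(n_ref, n - n_ref))[sample.int(n)]
    anchor_ref <- sample(serum$sample_id[batch == "reference"], config$n_anchor_samples)
    bfac <- exp(runif(M, log(config$batch_scale_range[1]),
                      log(config$batch_scale_range[2])))

    rerun <- intens[match(anchor_ref, serum$sample_id), , drop = FALSE] *
      exp(matrix(rnorm(config$n_anchor_samples * M, 0, config$anchor_noise_sd),
                 config$n_anchor_samples, M))
    rerun_id <- paste0(anchor_ref, "_rerun")
    all_int <- rbind(intens, rerun)
    rownames(all_int) <- c(serum$sample_id, rerun_id)
    colnames(all_int) <- met_id
    all_batch <- c(batch, rep("target", config$n_anchor_samples))
    target_rows <- all_batch == "target"
    all_int[target_rows, ] <- sweep(all_int[target_rows, , drop = FALSE], 2, bfac, `*`)

    metab <- metabolite_matrix(
      all_int, batch = all_batch,
      anchor_pairs = data.frame(reference = anchor_ref, target = rerun_id,
                                stringsAsFactors = FALSE))
    truth <- list(planted_metabolite = planted_id, batch_factors = setNames(bfac, met_id),
                  collinear_block = setNames(block, met_id),
                  zero_rates = setNames(zr, met_id))
    list(metab = metab, truth = truth)
  })
}

#' Simulate a complete synthetic trial
#'
#' Runs [simulate_cohort()], [simulate_microbiome()], [simulate_outcomes()]
#' and [simulate_metabolome()] in order, attaches outcomes to the metadata,
#' and returns everything with the combined ground truth.
#'
#' @param config a [sim_config()].
#' @return A list with `meta`, `counts` (ASV [count_table()]), `outcomes`,
#'   `metab` ([metabolite_matrix()]), and `truth`.
#' @examples
#' sim <- simulate_trial(sim_config(n_patients = 12, n_metabolites = 40,
#'                                  n_anchor_samples = 4, seed = 7))
#' table(sim$meta$arm[!duplicated(sim$meta$patient_id)])
#' @export
simulate_trial <- function(config = sim_config()) {
  meta <- simulate_cohort(config)
  mic <- simulate_microbiome(meta, config)
  outcomes <- simulate_outcomes(meta, mic$counts, config)
  meta$outcome <- outcomes$outcome[match(meta$patient_id, outcomes$patient_id)]
  meta$outcome[meta$role == "donor"] <- NA_integer_
  met <- simulate_metabolome(meta, outcomes, config)
  truth <- c(mic$truth, met$truth,
             list(outcome_alpha = attr(outcomes, "alpha"),
                  planted_feature_ids = c(genus = config$planted_genus,
                                          metabolite = met$truth$planted_metabolite)))
  list(meta = meta, counts = mic$counts, outcomes = outcomes,
       metab = met$metab, truth = truth, config = config)
}

#' Write a simulated trial to disk
#'
#' Writes the ASV count TSV, taxonomy TSV, metadata TSV, metabolite TSV
#' (with batch column and anchor-pair TSV) and a ground-truth JSON into
#' `dir`.
#'
#' @param sim result of [simulate_trial()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(sim$counts, file.path(dir, "asv_counts.tsv"),
                    taxonomy_path = file.path(dir, "taxonomy.tsv"))
  utils::write.table(sim$meta, file.path(dir, "sample_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mm <- data.frame(sample_id = rownames(sim$metab$intensities),
                   batch = sim$metab$batch, sim$metab$intensities,
                   check.names = FALSE)
  utils::write.table(mm, file.path(dir, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$metab$anchor_pairs, file.path(dir, "anchor_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$true_topic_term <- as.data.frame(truth$true_topic_term)
  truth$true_sample_topics <- as.data.frame(truth$true_sample_topics)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
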