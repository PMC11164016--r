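test_that("randomization allocates the 2:1 ratio exactly", {
  meta <- simulate_cohort(sim_config(seed = 1))
  pat <- meta[meta$role == "patient" & !duplicated(meta$patient_id), ]
  expect_equal(sum(pat$arm == "FMT"), 49)
  expect_equal(sum(pat$arm == "placebo"), 25)
  meta3 <- simulate_cohort(sim_config(n_patients = 3, n_metabolites = 20,
                                      n_anchor_samples = 2, seed = 2))
  pat3 <- meta3[meta3$role == "patient" & !duplicated(meta3$patient_id), ]
  expect_equal(as.vector(table(pat3$arm)[c("FMT", "placebo")]), c(2L, 1L))
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(arm_ratio = c(2, -1)), "ratio")
})

test_that("cohort structure matches the trial design", {
  cfg <- sim_config(seed = 5)
  meta <- simulate_cohort(cfg)
  expect_silent(validate_sample_meta(meta))
  # donors: one stool sample each, no arm/outcome
  d <- meta[meta$role == "donor", ]
  expect_equal(nrow(d), 4)
  expect_true(all(is.na(d$arm)))
  # FMT patients have an assigned donor, placebo patients none
  pat <- meta[meta$role == "patient" & !duplicated(meta$patient_id), ]
  expect_true(all(!is.na(pat$donor_id[pat$arm == "FMT"])))
  expect_true(all(is.na(pat$donor_id[pat$arm == "placebo"])))
  # both assays present with the configured timepoints
  expect_setequal(unique(meta$timepoint[meta$assay == "serum"]),
                  names(cfg$serum_retention))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11, n_patients = 20, n_metabolites = 40,
                    n_anchor_samples = 5)
  s1 <- simulate_trial(cfg)
  s2 <- simulate_trial(cfg)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$metab$intensities, s2$metab$intensities)
  expect_identical(s1$outcomes$outcome, s2$outcomes$outcome)
})

test_that("count and intensity matrices satisfy their type contracts", {
  sim <- simulate_trial(sim_config(seed = 12, n_patients = 15,
                                   n_metabolites = 30, n_anchor_samples = 4))
  expect_true(all(sim$counts$counts >= 0))
  expect_equal(sim$counts$counts, round(sim$counts$counts))
  expect_true(all(sim$metab$intensities >= 0))
  expect_true(all(rowSums(sim$truth$true_sample_topics) - 1 < 1e-8))
  expect_true(all(abs(rowSums(sim$truth$true_topic_term) - 1) < 1e-8))
  expect_true(all(sim$outcomes$outcome %in% c(0, 1)))
})

test_that("zero engraftment shares no donor-private ASVs with recipients", {
  cfg <- sim_config(seed = 13, engraftment_rate = 0)
  sim <- simulate_trial(cfg)
  priv <- unlist(sim$truth$donor_private_sets)
  post <- sim$meta$sample_id[sim$meta$assay == "stool" & !is.na(sim$meta$arm) &
                               sim$meta$arm == "FMT" &
                               sim$meta$timepoint %in% c("post10", "post28", "late")]
  counts <- sim$counts$counts[post, , drop = FALSE]
  expect_equal(sum(counts[, colnames(counts) %in% priv]), 0)
})

test_that("full engraftment at deep sequencing carries every donor ASV", {
  cfg <- sim_config(seed = 14, engraftment_rate = 1,
                    depth_range = c(2e5, 2e5), frac_low_depth = 0)
  sim <- simulate_trial(cfg)
  meta <- sim$meta
  post <- meta[meta$assay == "stool" & !is.na(meta$arm) & meta$arm == "FMT" &
                 meta$timepoint %in% c("post10", "post28"), ]
  for (i in seq_len(min(10, nrow(post)))) {
    dset <- sim$truth$donor_asv_sets[[post$donor_id[i]]]
    present <- colnames(sim$counts$counts)[sim$counts$counts[post$sample_id[i], ] > 0]
    expect_true(all(dset %in% present))
  }
})

test_that("mean sample depth matches the log-uniform depth model", {
  cfg <- sim_config(seed = 15, n_patients = 150, frac_low_depth = 0,
                    timepoints = c("baseline", "pre", "post28"),
                    retention = c(baseline = 1, pre = 1, post28 = 1))
  meta <- simulate_cohort(cfg)
  mic <- simulate_microbiome(meta, cfg)
  tot <- rowSums(mic$counts$counts)
  # E[depth] for log-uniform on [a, b] is (b - a) / log(b / a)
  expected <- (5e4 - 5e3) / log(10)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 4 * se)
  # multinomial totals equal the drawn depths exactly
  expect_equal(unname(tot), unname(mic$truth$depth))
})

test_that("outcome model responds to the planted effect and calibrates alpha", {
  # null effect: no association between planted clr and outcome
  cfg0 <- sim_config(seed = 16, n_patients = 600, beta_outcome = 0,
                     gamma_prophylaxis = 0,
                     timepoints = c("post28"), retention = c(post28 = 1),
                     depth_range = c(2000, 5000))
  meta0 <- simulate_cohort(cfg0)
  mic0 <- simulate_microbiome(meta0, cfg0)
  out0 <- simulate_outcomes(meta0, mic0$counts, cfg0)
  rho0 <- suppressWarnings(cor(out0$clr_planted, out0$outcome,
                               method = "spearman"))
  expect_lt(abs(rho0), 0.1)
  expect_lt(abs(mean(out0$outcome) - 0.35), 0.06)
  # positive effect: positive association
  cfg1 <- sim_config(seed = 17, n_patients = 600, beta_outcome = 1.5,
                     timepoints = c("post28"), retention = c(post28 = 1),
                     depth_range = c(2000, 5000))
  meta1 <- simulate_cohort(cfg1)
  mic1 <- simulate_microbiome(meta1, cfg1)
  out1 <- simulate_outcomes(meta1, mic1$counts, cfg1)
  rho1 <- suppressWarnings(cor(out1$clr_planted, out1$outcome,
                               method = "spearman"))
  expect_gt(rho1, 0.15)
  # intercept calibration: expected rate hits the target exactly
  eta0 <- cfg1$beta_outcome * out1$clr_planted +
    cfg1$gamma_prophylaxis * out1$ptcy
  alpha <- attr(out1, "alpha")
  expect_equal(mean(plogis(alpha + eta0)), 0.35, tolerance = 1e-8)
  # empirical event rate at n = 10,000 Bernoulli draws
  set.seed(18)
  draws <- rbinom(10000, 1, sample(plogis(alpha + eta0), 10000, replace = TRUE))
  expect_lt(abs(mean(draws) - 0.35), 0.02)
})

test_that("metabolome emits 18 anchor pairs with identical identity", {
  sim <- simulate_trial(sim_config(seed = 19))
  ap <- sim$metab$anchor_pairs
  expect_equal(nrow(ap), 18)
  b <- sim$metab$batch
  ids <- rownames(sim$metab$intensities)
  expect_true(all(b[match(ap$reference, ids)] == "reference"))
  expect_true(all(b[match(ap$target, ids)] == "target"))
  # the rerun is the same biological sample (id provenance)
  expect_equal(ap$target, paste0(ap$reference, "_rerun"))
  expect_error(simulate_metabolome(sim$meta, sim$outcomes,
                                   sim_config(seed = 19, n_anchor_samples = 5000)),
               "exceeds")
})

test_that("unit batch factors with clean anchors leave ratios at one", {
  cfg <- sim_config(seed = 20, n_patients = 30, n_metabolites = 25,
                    n_anchor_samples = 6, batch_scale_range = c(1, 1),
                    anchor_noise_sd = 0, zero_rate = 0)
  sim <- simulate_trial(cfg)
  ap <- sim$metab$anchor_pairs
  ratios <- sim$metab$intensities[ap$reference, ] /
    sim$metab$intensities[ap$target, ]
  expect_equal(unname(as.vector(ratios)), rep(1, length(ratios)))
  adj <- batch_adjust(sim$metab)
  expect_equal(adj$intensities, sim$metab$intensities)
})

test_that("collinear blocks correlate and their absence leaves independence", {
  cfg <- sim_config(seed = 21, n_patients = 80, n_metabolites = 60,
                    n_anchor_samples = 6, zero_rate = 0)
  sim <- simulate_trial(cfg)
  blocks <- sim$truth$collinear_block
  x <- log(sim$metab$intensities)
  b1 <- names(blocks)[!is.na(blocks) & blocks == 1]
  rho <- cor(x[, b1], method = "spearman")
  expect_gt(min(rho[upper.tri(rho)]), 0.5)
  # frac_collinear = 0: off-diagonal correlations center near zero
  cfg0 <- sim_config(seed = 22, n_patients = 80, n_metabolites = 40,
                     n_anchor_samples = 6, frac_collinear = 0, zero_rate = 0)
  sim0 <- simulate_trial(cfg0)
  x0 <- log(sim0$metab$intensities)
  rho0 <- cor(x0, method = "spearman")
  off <- rho0[upper.tri(rho0)]
  expect_lt(abs(median(off)), 0.06)
  expect_lt(quantile(abs(off), 0.95), 0.3)
})

test_that("simulation artifacts round-trip through the writers", {
  sim <- simulate_trial(sim_config(seed = 23, n_patients = 8,
                                   n_metabolites = 15, n_anchor_samples = 3))
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("asv_counts.tsv", "taxonomy.tsv", "sample_meta.tsv",
      "metabolites.tsv", "anchor_pairs.tsv", "ground_truth.json")))))
  back <- read_count_table(file.path(dir, "asv_counts.tsv"),
                           taxonomy_path = file.path(dir, "taxonomy.tsv"))
  expect_equal(back$counts, sim$counts$counts)
})
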