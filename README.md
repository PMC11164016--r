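# fmtomics

Multi-omics analysis of randomized fecal microbiota transplantation (FMT)
trials in allogeneic hematopoietic cell transplantation, with paired serum
metabolomics. The scientific question the toolkit serves: does FMT
reshape the gut microbiome into donor-like subcommunities, do specific
engrafting taxa change the risk of grade II–IV acute graft-versus-host
disease (aGVHD), and is any of that mirrored in the blood metabolome?

The package is aimed at statisticians and computational microbiologists
analyzing trial-style multi-omics data: ASV count tables with taxonomy,
per-sample clinical metadata, and untargeted metabolite intensity
matrices with batch structure.

## What it implements

* **Compositional preprocessing** — read-depth filter (>1,000 reads),
  relative-abundance ASV filter (>0.1% in ≥2 samples), genus
  agglomeration with a 1% prevalence rule and higher-rank fallback for
  unassigned genera, early post-intervention timepoint selection.
* **Compositional statistics** — centered log-ratio (clr) transform,
  Aitchison distance, principal coordinates, one-factor PERMANOVA
  (Anderson's pseudo-F, seeded permutations, p = (1+r)/(n+1)), Wilcoxon
  comparisons with Bonferroni correction, `ward.D` sample grouping.
* **Microbial subcommunities** — latent Dirichlet allocation fitted by
  variational EM (estimated symmetric document concentration, smoothed
  topic-term MAP updates, random restarts), topic number chosen on a
  2–10 grid by the Cao density criterion.
* **Zero-sum log-ratio lasso** — logistic lasso under the constraint
  `sum(beta) = 0`, making predictions invariant to per-sample sequencing
  depth:

      minimize  (1/n) * sum_i [log(1 + exp(eta_i)) - y_i * eta_i] + lambda * ||beta||_1
      subject to  sum_j beta_j = 0,   eta = b0 + X beta + C theta

  solved by an augmented Lagrangian with IRLS + coordinate descent
  (Rcpp), with 4-fold cross-validated `lambda_min` and 100-run stability
  selection (per-feature selection probabilities and signs).
* **Metabolome preparation** — anchor-sample median-of-ratios batch
  adjustment, >25% non-detection filter, Spearman-rho > 0.5 collinearity
  pruning (one representative per connected component), half-minimum
  imputation, log transform and standardization.
* **Outcome models for metabolites** — stability-selected 10-fold
  cross-validated logistic lasso (glmnet) with an unpenalized PTCy
  prophylaxis covariate and fold-averaged coefficients at `lambda_min`;
  sparse PLS discriminant analysis tuned by balanced error rate; PCA.
* **Donor engraftment** — Jaccard presence/absence similarity of a
  genus's ASVs between each post-FMT patient and their donor, correlated
  with post-FMT abundance and pre-to-post change.
* **Cross-omics map** — Spearman correlations between selected taxa /
  cluster abundances and high-variance metabolites, masked at p < 0.05.
* **Synthetic trial generator** — a 74-patient, 2:1, 4-donor trial with
  three latent subcommunities, a donor-ASV engraftment process, a
  logistic outcome driven by one genus, and a two-batch metabolome with
  18 anchor samples and one planted protective metabolite; full ground
  truth returned for validation.

## Worked example

```r
library(fmtomics)

sim  <- simulate_trial(sim_config(seed = 3))
prep <- prep_microbiome(sim$counts)
prep$genus
#> count_table: 223 samples x 37 features
#>   total reads: 4,205,969; median depth: 14,771

sel <- select_k(prep$genus, k_min = 2, k_max = 6, seed = 5)
sel$k_star
#> [1] 3

ms <- sim$meta[sim$meta$assay == "stool" &
               sim$meta$sample_id %in% rownames(prep$asv$counts), ]
ea <- engraftment_analysis(prep$asv, ms, "Faecalibacterium")
round(c(rho = ea$rho_abundance, n = ea$n), 3)
#>    rho      n
#>  0.871 36.000
```

The topic model recovers the three planted subcommunities (the Cao
criterion is minimized at k = 3 at the default trial scale); the
engraftment analysis shows the strong positive correlation between the
fraction of donor ASVs shared and the post-FMT abundance of the planted
genus, the signature of abundance driven by engraftment. Stability
selection on the early post-intervention genus table
(`stability_select()`) ranks the planted genus first, with positive sign,
in essentially all of the 100 cross-validation runs.

The full analysis runs from one configuration:

```r
report <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "out")
report
#> fmtomics pipeline report (seed 1)
#>   topics: k* = 3
#>   PERMANOVA FMT vs placebo: p = 0.001
#>   ...
```

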