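---
title: "Methods: multi-omics analysis of a randomized FMT trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics analysis of a randomized FMT trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`fmtomics` implements the statistical machinery used to analyze a
randomized, placebo-controlled trial of oral-capsule fecal microbiota
transplantation (FMT) in allogeneic hematopoietic cell transplantation
(allo-HCT), where the clinical endpoint is grade II–IV acute
graft-versus-host disease (aGVHD). The package covers six analysis
pillars — compositional preprocessing of ASV count tables, latent
Dirichlet allocation (LDA) of microbial subcommunities, a zero-sum
log-ratio lasso with stability selection for taxon-level outcome
prediction, anchor-based batch normalization and QC of untargeted serum
metabolomics with stability-selected outcome models, an ASV-level
donor-engraftment similarity index, and a cross-omics Spearman
correlation map — plus a synthetic-trial generator with known ground
truth that makes every stage testable without access to patient data.

# The synthetic trial generator

The generator is a *model of the study design*, not of any patient. Its
defaults mirror the trial's structure: 74 patients randomized 2:1 to FMT
(49) or placebo (25), 4 stool donors assigned to FMT patients,
longitudinal stool sampling (baseline, pre-dose, day 10, day 28,
9 months) and serum sampling (baseline, pre-dose, day 28, 9 months) with
per-timepoint completely-at-random retention probabilities chosen to
reproduce the reported per-timepoint sample counts, a PTCy-based
prophylaxis label drawn with deliberately imbalanced per-arm
probabilities (0.45 FMT vs 0.76 placebo), and a two-batch 250-metabolite
serum panel with 18 anchor samples run in both batches.

Three generative mechanisms carry the planted signals:

* **Composition.** Each stool sample's genus composition is a mixture of
  three Dirichlet topic distributions. Anchor genera (e.g.
  *Faecalibacterium* and *Alistipes* for the commensal-anaerobe topic,
  *Bacteroides* for the second, *Streptococcus*/*Veillonella*/
  *Escherichia-Shigella* for the dysbiotic oral/proteobacterial topic)
  receive concentrated within-topic mass. Topic weights depend on role,
  arm and timepoint: donors and post-FMT samples weight topic 1 up,
  pre-dose samples weight topic 3 up. ASV counts are multinomial at a
  log-uniform depth in [5,000, 50,000], with 3% of samples re-drawn at
  200–1,000 reads to exercise the read-count filter.
* **Engraftment.** The planted genus has 12 private ASVs per donor plus a
  small cosmopolitan pool; each donor ASV establishes in a recipient
  after FMT with probability `engraftment_rate` (default 0.5), and every
  established ASV adds 0.035 relative abundance to the planted genus.
  Recipients otherwise carry only a two-ASV residual community of that
  genus (heavy pre-transplant loss). This makes donor-ASV sharing and
  post-FMT abundance positively coupled by construction; the constants
  were calibrated once, at large n, so that the Spearman correlation
  between Jaccard similarity and post-FMT abundance is ≈ 0.85 (the
  study-condition analogue of a strong engraftment signal), and then
  frozen.
* **Outcome and metabolome.** The aGVHD indicator is Bernoulli with
  logit `alpha + 1.5 * clr(planted genus at early post) + 0.5 * PTCy`,
  with `alpha` calibrated by root finding so the marginal event rate is
  0.35 (the order of magnitude of grade II–IV aGVHD incidence).
  Metabolite log intensities are Gaussian (log-normal intensities);
  30% of the panel sits in correlated blocks of ~5 sharing a latent
  factor (loading 0.85, so within-block Spearman > 0.5 by construction);
  non-detections are injected by left-censoring at per-metabolite rates
  uniform on [0, 0.3]; the target batch is scaled by per-metabolite
  factors in [0.5, 2]; and one block-free metabolite is shifted by
  −1.5 log units in early post-intervention samples of patients who
  develop aGVHD. The shift is generated conditionally on the outcome
  (outcome first, metabolite second); under a Gaussian class-conditional
  model this is equivalent to a logistic effect of the metabolite on the
  outcome of the same magnitude, and −1.5 standard deviations represents
  a strongly, stably selectable protective metabolite.

What the generator does **not** emulate: read-level error profiles and
denoising (tables are emitted at ASV level directly), strain phylogenies,
real inter-genus covariance beyond the topic structure, longitudinal
autocorrelation within patients beyond the timepoint means, and
non-multiplicative batch distortions. Passing tests therefore demonstrate
correctness of the *procedures* under the design assumptions each
procedure itself makes, not performance on real sequencing data.

# Microbiome preprocessing

Filters run in the order samples → ASVs → genera: samples with more than
1,000 reads are retained (strict inequality); ASVs with within-sample
relative abundance above 0.1% in at least two samples are retained, with
denominators recomputed after the sample filter; ASV counts are then
summed per genus, and genera present (nonzero) in at least
`ceiling(0.01 * n)` samples are kept. ASVs without a genus assignment are
promoted to their best assigned higher rank (e.g. "Lachnospiraceae
Family"), so their counts are not lost. For outcome analyses the early
post-intervention sample is the day-28 sample when present, otherwise the
day-10 sample. The 1% prevalence denominator includes all loaded samples
(donors included); this is configurable because the convention is not
universal.

# Compositional statistics

The clr transform adds a pseudocount (default 0.5, the common
Bayes-multiplicative choice for counts; use a small floor like `1e-6` for
probability-scale inputs such as topic abundances), closes rows to
proportions, and centers logs per sample; the Aitchison distance is the
Euclidean distance between clr rows. PERMANOVA uses Anderson's
pseudo-F computed directly from the squared distance matrix, with the
permutation p-value `(1 + #{F_perm >= F_obs}) / (n_perm + 1)` over seeded
raw-label permutations (no strata). Group comparisons use the two-sided
Wilcoxon rank-sum test (exact for ≤10 per group without ties, otherwise
the tie-corrected normal approximation) with optional Bonferroni
correction. Sample groups are formed by `ward.D` hierarchical clustering
(classic Ward update on unsquared Euclidean distances, matching the
`ward.D` option of `hclust`) of per-cluster-scaled topic abundances.

# Topic modeling

`fit_lda()` is a variational EM implementation of LDA with samples as
documents and genera as words. The E-step alternates the closed-form
responsibilities and Dirichlet parameters (vectorized across samples;
responsibilities are invariant to per-sample scaling of
`exp(digamma(gamma))`, which is exploited for numerical stability); the
M-step applies a MAP topic-term update with smoothing `eta = 0.1` and
re-estimates the symmetric document concentration `alpha` by safeguarded
Newton steps. Because early concentration estimates mostly reflect the
initialization, `alpha` updates begin after a 10-iteration burn-in;
without it the fit can lock into a poor hard assignment (we observed
total-variation recovery error of ~0.2 instead of ~0.02 on
disjoint-support data). Each fit uses 5 random restarts keeping the best
objective; the tracked objective (variational bound plus topic-term log
prior) is non-decreasing, which the tests assert. The number of topics is
selected over 2–10 by the Cao density criterion (mean pairwise cosine
similarity of topic-term rows, minimized; ties go to the smaller k).
Topic labels are arbitrary, so all reporting is permutation-invariant.

# Zero-sum log-ratio lasso

`fit_zero_sum()` minimizes mean binomial deviance plus an L1 penalty
subject to the penalized coefficients summing to zero. Under that
constraint the linear predictor depends only on log-ratios between
features, so fitted probabilities are invariant to per-sample sequencing
depth (tested end-to-end from counts). The solver is an augmented
Lagrangian: IRLS with cyclic coordinate descent and soft thresholding
minimizes the penalized working quadratic at fixed multiplier, then the
multiplier is updated and the penalty escalated (×10, at most 8 rounds)
until the constraint residual is below 1e-6. Two implementation choices
matter numerically: the multiplier is warm-started along the descending
lambda path (later lambdas typically need one round), and the penalty
parameter starts at `1/p` rather than 1 — the constraint contributes a
rank-one term `rho * (sum beta)^2` to the working Hessian, and with
`rho ~ 1` cyclic coordinate descent contracts at roughly 0.97 per sweep,
while `1/p` keeps the subproblem well conditioned. Solutions match a
multi-started Nelder-Mead oracle on the constraint-eliminated
parameterization to ~1e-8 in objective.

Cross-validation uses stratified folds (with few events per fold,
unstratified splits can produce single-class folds), a log-spaced grid of
lambdas spanning four decades below the smallest all-zero penalty
`(max g - min g)/2` (g the null-model gradient), and mean held-out
binomial deviance. The grid is evaluated in expanding chunks, stopping
once the deviance minimum is interior — identical answers, far less time
in the near-saturated tail. Stability selection repeats the whole
procedure with fresh fold partitions, refits on the full data at each
run's `lambda_min`, and reports per-feature selection probabilities with
signs; ranking is by probability, then absolute mean coefficient, then
feature id.

**The null reference.** For a *fixed* dataset the full-data path does not
change between runs, so a feature's selection probability is exactly the
probability that `lambda_min` falls below its entry point. A single fixed
permutation of the outcome is therefore not a useful null: the permuted
outcome retains chance associations that cross-validate within that
dataset, and the earliest-entering feature reaches probability near 1
regardless of implementation. The meaningful null re-permutes the outcome
independently in every run (`null_permute = TRUE`), drawing a fresh
realization of the no-association hypothesis each time; under it no
feature should appear stable, and the tests assert exactly that.

# Metabolome preprocessing

The pipeline order is batch adjustment → detection filter → collinearity
pruning → half-minimum imputation → log transform/standardization. Batch
adjustment computes, per metabolite, the median over anchor pairs of the
reference/target ratio (pairs with a non-detection on either side are
excluded) and multiplies target-batch values by it; a metabolite with
fewer than 3 clean anchor pairs falls back to the global median ratio,
and a global-factor mode is available. Per-metabolite factors are the
standard reading for intensity data, where batch effects are
compound-specific. The detection filter drops metabolites undetected in
strictly more than 25% of samples. Collinearity pruning builds the graph
of signed Spearman correlations above 0.5 (an `absolute` flag is
available), finds connected components by union-find, and keeps the
member with the highest log-scale variance (zeros half-minimum
substituted for this ranking only), ties broken lexicographically.
Representatives of *different* components may still correlate above the
threshold; this is logged, not forbidden, because component-wise
representation is what "keep one member of every collinear set" defines.
Half-minimum imputation replaces zeros by half the minimum nonzero value
of that metabolite across all samples; logs are natural; standardization
uses the n−1 standard deviation.

# Outcome models

The metabolite-level lasso follows the glmnet route: binomial lasso over
a shared lambda grid, stratified 10-fold cross-validation per repeat,
`lambda_min` by mean held-out deviance, and — taken literally from the
described procedure — the ten *per-fold* coefficient vectors at
`lambda_min` averaged; a feature is selected in a repeat when its
averaged coefficient is nonzero. The PTCy-based prophylaxis indicator
enters with penalty factor 0 so it can never be shrunk away. One hundred
repeats with fresh partitions give selection probabilities and signs
(negative = protective).

sPLS-DA uses the standard sparse-PLS scheme: per component the weight
vector is the soft-thresholded `X'y` direction keeping the top-`keepX`
magnitudes, normalized to unit L2 norm; scores deflate both X and the
class code; classification is by centroid distance in score space;
prediction of new samples uses the `W (P'W)^{-1}` projection. Tuning
minimizes the mean balanced error rate over repeated stratified 4-fold
CV, sequentially per component over `keepX` in {5, 10, 20, 50} and then
over the number of components (max 2). This follows the published
sparse-PLS algorithm rather than replicating any specific implementation
bit-for-bit; a test checks component-1 loadings agree with
`mixOmics::splsda` up to sign on a toy problem. PCA scores use `prcomp`
with a deterministic sign convention (largest-magnitude loading
positive).

# Engraftment similarity

For each FMT patient with an early post-FMT sample and an assigned donor,
the ASV table (after the standard filters) is restricted to one genus;
presence is any nonzero count; and similarity is the Jaccard index of the
patient's and donor's ASV sets. Jaccard is the "fraction of shared ASVs"
reading of a presence/absence similarity, ignoring joint absences; Dice
and simple-matching variants are provided behind a flag. The analysis
reports Spearman correlations of similarity against both the post-FMT
relative abundance and the pre-to-post change, since both appear in the
source analyses and the text does not disambiguate which one the headline
correlation used.

# Cross-omics map

Row features are clr-transformed genus abundances of the union of each
topic's top-5 genera plus the topic abundances themselves; column
features are the 50 highest-variance log metabolites plus any pinned ids
(e.g. the stability-selected metabolite). Pairs are matched by patient at
the early post-intervention timepoint. Spearman rho and two-sided p are
reported per pair with a significance mask at unadjusted p < 0.05,
matching the hypothesis-generating framing of the source analysis; an
FDR-adjusted mode is available but off by default.

# Pipeline, seeds and problem sizes

`run_pipeline()` executes the stages in dependency order from one nested
configuration (R list or YAML), with a single global seed fanned out into
per-stage seeds through a counter scheme, so disabling one stage never
shifts another stage's random stream; the report JSON is byte-identical
across reruns of the same configuration and seed. The test suite runs the
heavier simulation checks at deliberately chosen problem sizes — 20
replicates of the topic-number search at 200 samples × 10,000 reads, ten
simulated trials at the default 74-patient scale for each stability
criterion with a 20-point lambda grid, 500 simulated datasets for the
PERMANOVA null — sizes at which the Monte-Carlo error of each check is
comfortably below the margin it asserts.

# Known limitations

* The LDA objective uses the MAP topic-term estimate rather than a full
  variational Dirichlet over topics; with `eta = 0.1` the difference is
  negligible at these data sizes but the bound is not the classical fully
  Bayesian one.
* The zero-sum solver targets binomial outcomes only; survival and
  competing-risk endpoints are out of scope.
* The sPLS-DA tuning reports Monte-Carlo means and standard deviations of
  the balanced error rate; it does not compute permutation p-values.
* `prune_collinear` treats constant metabolites as uncorrelated (with a
  warning) rather than dropping them; the detection filter upstream makes
  all-constant columns unlikely.
* The generator's missingness is completely at random; informative
  dropout (e.g. sicker patients missing later samples) is not modeled.
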