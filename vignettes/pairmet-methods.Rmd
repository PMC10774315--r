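---
title: "Methods: mechanism-constrained rank-pair signatures of metastasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanism-constrained rank-pair signatures of metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairmet)
```

## The problem

Aggressive, neuroendocrine-prone prostate tumors reshape their mesenchymal
stroma. The transcriptional programs of these stromal subpopulations can be
read out from single-cell RNA-seq, and — because they accompany disease
progression — they carry prognostic information that is measurable in bulk
tumor expression profiles. `pairmet` implements the full chain from stromal
cluster markers to a clinically evaluable classifier:

1. **Markers.** Per stromal cluster, differential expression against all
   other cells pooled, with a two-part hurdle model suited to zero-inflated
   single-cell data.
2. **Mechanism.** Up-regulated markers are paired with down-regulated markers
   of the same cluster. Each ordered pair `(up, down)` encodes the
   expectation that `up` out-ranks `down` when the stromal program is active.
3. **Classifier.** A k-top-scoring-pairs (k-TSP) model restricted to the
   mechanism pairs, trained on harmonized multi-cohort bulk data to predict
   metastasis, and applied by majority vote over within-sample gene
   comparisons.
4. **Evaluation.** AUROC on a held-out partition; a logistic probability
   score over the signature genes; Kaplan–Meier curves, the log-rank test and
   a Gleason-adjusted Cox proportional-hazards model on progression-free
   survival (PFS).

Because every k-TSP statistic depends only on within-sample orderings, the
classifier is invariant to any monotone per-sample normalization — the
property that makes rank-pair signatures portable across expression
platforms.

## The hurdle model

For one gene, log-normalized expression \(x\) (library-size scaled to
10,000 counts, then \(\log(1+x)\)) is modeled in two parts given a binary
group indicator \(g\):

* **Detection**: \(\Pr(x > 0) = \operatorname{logit}^{-1}(\alpha_0 +
  \alpha_1 g)\);
* **Continuous**: among detected cells, \(x \mid x>0 \sim
  N(\beta_0 + \beta_1 g, \sigma^2)\) with a common variance.

With a single binary covariate both parts have closed-form maximum-likelihood
solutions (a 2×2 detection table and group means with the pooled MLE
variance), so the joint likelihood-ratio statistic — the sum of the two
component LRTs, referred to \(\chi^2_2\) — is computed exactly rather than by
iterative fitting. When one group has no detected cells the continuous part
is dropped and the reference becomes \(\chi^2_1\), flagged in the output.
The implementation deliberately omits a cellular-detection-rate covariate;
this keeps the closed forms exact and testable against independent
`glm`/`lm` oracles, and is an explicit design choice documented here as an
extension point rather than a default.

Markers are prefiltered *before* testing, and the number of tests entering
Benjamini–Hochberg correction equals the number of reported rows:

* average fold change
  \(\left|\,\ln(\bar e_{\text{in}}+1) - \ln(\bar e_{\text{out}}+1)\,\right|
  \ge 0.25\), where \(\bar e\) is the mean of `expm1(x)` per group
  (natural-log scale, the dominant single-cell convention for this
  threshold);
* detection in at least 10% of cells in either group.

Downstream use gates markers at FDR < 0.05 (a conventional choice).

## Mechanism construction

Per cluster, the top `n_top = 100` positive markers (by descending average
logFC) and top 100 negative markers (ascending) form all positive × negative
ordered pairs; ties in logFC at the boundary break lexicographically by gene
id so results are reproducible. Three clusters with full marker lists give
3 × 100 × 100 = 30,000 cluster-tagged pairs. Training uses the deduplicated
pooled set; the cluster-tagged multiset is retained for audit. A cluster
without markers of one sign contributes no pairs (with a warning), never an
error.

## Cohort harmonization and splitting

Datasets are harmonized exactly in the order narrated by the method: each
dataset is (if linear) log2-transformed, z-scored gene-wise, gene sets are
intersected, samples concatenated; then the cohort is split 75/25 and each
partition is quantile-normalized *separately*. The split is stratified on
dataset × Gleason × age tertile × PSA tertile × stage; continuous variables
are binned into tertiles computed on the full cohort (the variables are
prescribed, the binning is our choice), missing values form an explicit
"unknown" level so the partition stays exhaustive, and per-stratum
allocations use largest-remainder rounding with the global training count
forced to \(\lceil 0.75\,n\rceil\) — a 1,239-sample cohort yields 930/309.
Strata of size 1 go wholly to training. Quantile normalization maps each
sample to the mean order-statistic profile, ties receiving the average of
their target quantiles (the standard convention; `limma` implements it).

## The k-TSP classifier

For each mechanism pair, the primary score is
\[
\Delta = \widehat{\Pr}(e_{\text{up}} > e_{\text{down}} \mid \text{met})
       - \widehat{\Pr}(e_{\text{up}} > e_{\text{down}} \mid \text{non-met}),
\]
with exact expression ties counting one half. The secondary score
\(\Gamma\) is the absolute between-class difference of the mean
within-sample rank difference, the standard tie-breaker in this algorithm
family. Selection scans candidates in order (\(\Delta\) desc, \(\Gamma\)
desc, lexicographic gene ids) and greedily keeps gene-disjoint pairs until
`k` are found. Pairs with \(\Delta \le 0\) are discarded: the mechanism
fixes the orientation expected in metastatic samples, so only positively
scoring pairs are admissible. Prediction is the mean pair vote
(1 if up > down, 0 if <, 0.5 on ties); a sample is called metastatic when
the vote fraction reaches 0.5 (the tie-at-0.5 rule favors sensitivity and
is configurable).

The default signature size is `k = 13` pairs (26 genes), the size of the
published stromal signature this pipeline re-derives. Alternatively
`choose_k()` selects `k` by 5-fold stratified cross-validation over odd
`k ∈ {3, …, 25}`, returning the smallest maximizer of mean held-fold AUROC;
the pipeline uses the fixed default so that the reported signature has a
defined size, and exposes CV selection through configuration (`k = NULL`).

## Survival evaluation

A logistic model over the 2k signature genes, fit on the training partition
only, produces a per-sample probability score; binarized at 0.5 it defines
predicted classes whose PFS is compared by Kaplan–Meier curves and the
log-rank test. The Gleason-adjusted Cox proportional-hazards model
(categorical Gleason, `<=6` as reference, Efron tie correction, Wald 95%
CIs) quantifies the signature's independent prognostic value. These standard
estimators are delegated to the `survival` package behind the module's
interfaces; the test suite validates them against hand-computed
product-limit values, the observed-minus-expected log-rank formula, and
grid-search maximization of the partial likelihood.

## The synthetic cohort generator

The generator produces inputs with the statistical structure the analysis
assumes — not a faithful scRNA-seq or microarray emulator — plus the ground
truth needed for recovery tests.

* **Single cells**: negative-binomial counts (shared dispersion 0.5) with
  multiplicative Bernoulli dropout (rate 0.3), the simplest law exhibiting
  the zero inflation and bimodality the hurdle model targets. A planted
  marker shifts its gene's NB log-mean by `logfc` in its cluster. Defaults:
  three marker-bearing mesenchymal clusters of 250 cells plus a 750-cell
  background cluster, 2,000 genes.
* **Bulk cohorts**: Gaussian log-scale expression (sd 1) across 600 samples
  in three datasets, balanced metastasis prevalence, per-dataset per-gene
  additive shifts (sd 0.4) and lognormal scales (sdlog 0.2) — exactly the
  batch structure that per-dataset z-scoring removes. Gleason is sampled
  from a categorical distribution tilted by a configurable log-odds per
  grade step in metastatic samples, so Gleason-adjusted models are
  non-trivially testable; the Gleason–metastasis association strength is a
  configurable assumption, not an inferred quantity.
* **Planted pairs**: each of the 13 default pairs receives a class-dependent
  offset \(\delta_c = \sqrt{2(1-\rho)}\,\sigma\,\Phi^{-1}(t_c)\) so that
  \(\Pr(\text{up} > \text{down})\) equals the target \(t_c\) (0.65
  metastatic / 0.35 non-metastatic) exactly under the Gaussian noise model.
  The two genes of a pair share their baseline and carry correlated noise
  (\(\rho = 0.9\) by default): a planted pair models a tightly co-regulated
  gene pair, so the inversion signal is a property of the *pair*, which is
  what a rank-pair classifier exploits and what makes pair identity
  statistically recoverable at all. With independent noise (\(\rho = 0\),
  also available), cross-pairings of planted genes would be exchangeable
  with the planted pairs and no method could tell them apart.
* **Survival**: exponential PFS with hazard
  \(\lambda_0 \exp(\beta\,\text{met} + \gamma\,\text{Gleason step})\)
  (defaults \(\lambda_0 = 0.02\)/month, \(\beta = \ln 2\),
  \(\gamma = 0.3\)) and independent exponential censoring (rate
  0.015/month). Medians and hazard ratios then have closed forms for
  recovery tests.

What passing tests on this generator demonstrate: the estimators are
correct (they match closed forms and brute-force oracles), the pipeline is
leak-free, and planted signal of realistic strength is recovered. What they
do not demonstrate: performance on real cohorts, where dropout is
gene-dependent, batch effects are not purely location/scale, pair noise
correlation varies, and censoring is informative. The generator makes no
attempt to emulate ambient RNA, doublets, UMI saturation, probe effects or
platform-specific distributions.

## Numerical choices and edge cases

* Hurdle LRT components are clamped at 0; a continuous part with zero pooled
  variance contributes 0 when the null variance is also 0 (identical
  groups).
* Detection log-odds differences may be infinite when a group is fully
  (un)detected; the LRT remains finite and is what downstream ranking uses.
* Quantile normalization of a single sample is a warning, not an error.
* `stratified_split` is deterministic given its seed; the within-stratum
  draw uses R's default generator.
* Cox fits refuse monotone likelihoods (all events in one covariate level)
  and non-convergence within 100 Newton–Raphson iterations, and report the
  complete-case count when covariates are missing.
* Logistic fits detect separation and direct the user to the ridge option
  (an in-package IRLS with an unpenalized intercept).
* A validation-cohort gene missing from a trained model's gene set is an
  error naming the gene; no imputation is attempted.

## Problem sizes used in the test suite

Oracle-equivalence suites run on instances of at most 40 cells per group,
12 samples and 30 candidate pairs, where exhaustive enumeration is exact.
Recovery and calibration suites use the default study conditions (2,000
genes, 600 samples, 13 pairs) across 50 seeds, null pipelines at 300 genes
and 240 samples across 20 seeds, 1,000 simulated null cohorts for log-rank
type-I error, and 50 seeds of 1,000-sample cohorts for twofold-hazard
recovery. These sizes were chosen so each property is measured with small
Monte-Carlo error while the whole suite stays fast enough to run routinely.

## Known limitations

* The hurdle model omits the cellular-detection-rate covariate that some
  reference implementations include by default.
* Ranks for the \(\Gamma\) score are computed over all genes in the cohort,
  so \(\Gamma\) (not \(\Delta\)) changes if the gene universe changes.
* The stratified split treats continuous covariates through cohort-level
  tertiles; finer binning or score-based matching is out of scope.
* Real-data mode expects pre-curated TSV inputs (one expression and one
  metadata table per dataset); no GEO/TCGA retrieval or probe-to-gene
  mapping is provided.
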