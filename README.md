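# pairmet

Mechanism-constrained k-top-scoring-pairs (k-TSP) signatures of metastasis
in prostate cancer, from stromal single-cell markers to survival evaluation.

Aggressive prostate tumors remodel their mesenchymal stroma, and the
transcriptional programs of those stromal subpopulations are prognostic.
`pairmet` is for computational biologists who want to turn cluster markers
from single-cell RNA-seq into a rank-based gene-pair classifier of
metastasis that transfers across bulk expression cohorts, and to evaluate it
on discrimination (AUROC) and progression-free survival (Kaplan–Meier,
log-rank, Gleason-adjusted Cox regression).

## The method in brief

1. **Hurdle markers.** Per stromal cluster vs all other cells: a two-part
   model — logistic detection plus Gaussian expression conditional on
   detection — tested jointly by a χ² likelihood ratio, after prefiltering
   to genes with |avg logFC| ≥ 0.25 (natural log) detected in ≥ 10% of
   cells in either group, then Benjamini–Hochberg FDR.
2. **Mechanism.** Top 100 positive × top 100 negative markers per cluster
   form ordered (up, down) candidate pairs (30,000 for three full clusters).
3. **k-TSP.** Each candidate pair is scored by
   Δ = P̂(up > down | met) − P̂(up > down | non-met); gene-disjoint pairs
   are selected greedily (Δ, then a rank-difference tie-break Γ) up to
   k = 13 pairs; a sample is called metastatic when the majority of pairs
   vote up > down. Votes depend only on within-sample rankings, so the
   classifier is invariant to monotone per-sample normalization.
4. **Cohorts.** Datasets are z-scored gene-wise per dataset, intersected,
   split 75/25 with stratification (dataset, Gleason, age, PSA, stage) and
   largest-remainder allocation, then quantile-normalized per partition.
5. **Evaluation.** AUROC; logistic probability scoring over the signature
   genes; Kaplan–Meier + log-rank between predicted classes; Cox
   proportional hazards adjusted for categorical Gleason (≤6 reference,
   Efron ties).

A calibrated synthetic-data generator (negative-binomial single cells with
dropout; Gaussian bulk cohorts with batch location/scale effects, planted
probit-calibrated rank-inverting pairs, and exponential censored survival)
supplies inputs and ground truth for every test.

## Worked example

```r
library(pairmet)

report <- run_pipeline(pipeline_config(seed = 42))
report
#> <evaluation_report> k = 13 pairs (26 genes)
#>   AUROC train 0.958 / test 0.935
#>   log-rank chi-square 11.528, p = 0.000685
#>   Gleason-adjusted signature HR 1.814 [1.232, 2.672]
```

Under the default study conditions (2,000 genes; three 250-cell stromal
clusters carrying planted markers; a 600-sample, three-dataset bulk cohort
with 13 planted pairs inverting with probability 0.65 in metastatic vs 0.35
in non-metastatic samples), the run above derives hurdle markers, builds the
pair mechanism, trains the 13-pair signature on the 450-sample training
partition, and reports: held-out discrimination (test AUROC 0.935), a
significant progression-free-survival separation between predicted classes
(log-rank p ≈ 7e-4), and a Gleason-adjusted hazard ratio of 1.81 for the
signature's predicted class. All 13 planted pairs are recovered in this run
(`report$signature` vs `report$truth$bulk$pairs`).

Individual stages are exported and composable: `simulate_single_cell()`,
`rank_markers()`, `build_mechanism()`, `harmonize()`, `stratified_split()`,
`quantile_normalize()`, `score_pairs()`, `select_pairs()`, `choose_k()`,
`predict()`, `auroc()`, `fit_logistic()`, `kaplan_meier()`, `logrank()`,
`cox_ph()`. A thin CLI lives at `inst/cli/pairmet.R`
(`Rscript inst/cli/pairmet.R run --config cfg.yaml --out out/ --seed 42`).

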