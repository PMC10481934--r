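# tilquant

Quantifying **intratumoral tumor-infiltrating lymphocytes (TILs)** from bulk
breast-cancer transcriptomes, and testing what that quantity is associated
with.

Pathologists score *stromal* TILs on tissue sections, but lymphocytes in
direct contact with cancer cells (*intratumoral* TILs) are too sparse to
count reliably by eye. When a bulk RNA-seq sample is taken from a
tumor-cell-rich region, the lymphocyte signal in its transcriptome is an
objective, quantitative readout of those intratumoral TILs. `tilquant`
implements that readout and the analysis battery built on it:

- **Cell-type scoring** — single-sample gene-set enrichment (ssGSEA) of
  cell-type marker signatures. For one sample with genes ranked
  `r(g)` (highest expression = rank `n`), a signature `S` scores

  `score(S) = Σ_i [ P_in^w(i) − P_out(i) ]`,

  where `P_in^w` is the rank-weighted (`r^α`, α = 0.25) in-set cumulative
  distribution and `P_out` the uniform ECDF of out-of-set genes. A cell
  type's score averages its signatures, is calibrated to `[0, 1]` over the
  cohort, and is spillover-compensated by solving
  `S_obs = S_true (I + κ(K − I))` with clamping at 0.
- **TIL score** — the sum of the 19 lymphocyte cell-type scores
  (CD4/CD8 T-cell subsets, Tregs, Th1/Th2, B-cell subsets, NK, NKT);
  displayed as `log2(score + ε)`. Cohorts are dichotomized into TIL-high /
  TIL-low at the **per-subtype median** (`score ≥ median → high`).
- **Estimator concordance** — Spearman correlation of candidate summaries
  (whole-lymphocyte and whole-T-cell sums per estimator) against lymphocyte
  marker genes (*CD3D, CD4, CD8A, FOXP3, PDCD1*) and the pathology TIL
  fraction, with argmax-row-mean selection.
- **Two-class GSEA** — signal-to-noise ranking, weighted-KS enrichment
  score, phenotype-permutation NES, and ratio-of-tails FDR q-values
  (significant at q < 0.25).
- **Outcome statistics** — cytolytic activity `CYT = √(GZMA·PRF1)` (linear
  scale), rank-sum and Kruskal-Wallis comparisons, Fisher tests of
  pathological complete response (pCR), and Kaplan-Meier / log-rank /
  hazard-ratio survival analysis per subtype.
- **Synthetic cohorts** — a generator that emulates the statistical
  structure this analysis assumes (lymphocyte abundance ordered
  TNBC > HER2+ > ER+/HER2−, dominant cancer-cell fraction, wide TIL
  dispersion, TIL-linked pCR odds and grade, subtype-specific TIL-group
  survival hazards), so every stage is testable without any download.

## Worked example

```r
library(tilquant)

panel  <- generate_reference_panel(seed = 1)           # 29 cell types, 500 genes
cohort <- simulate_cohort(panel, sim_config(seed = 2)) # 220 samples, 3 subtypes

scores <- score_cell_types(
  cohort$expression, panel$signatures,
  scoring_config(spillover_matrix = default_spillover_matrix(panel)))

til <- dichotomize_by_median(
  compute_til_score(scores, subtype = cohort$truth$subtype))

cor(til$raw, cohort$truth$true_til_fraction, method = "spearman")
#> [1] 0.9278419

tapply(til$log2, til$subtype, median)
#> ER_HER2neg    HER2pos       TNBC
#>   1.881876   2.056439   2.317903
```

The composite TIL score ranks samples almost exactly as the true simulated
lymphocyte fraction does (Spearman 0.93), and the median display score
reproduces the expected subtype ordering (TNBC highest, ER+/HER2− lowest).

```r
groups <- setNames(til$group, til$sample_id)
meta   <- truth_to_clinical(cohort$truth)
meta$cyt <- cyt_score(cohort$expression)[meta$sample_id]

compare_by_til_group(meta, groups, "cyt")[, c("subtype", "p_value", "stars")]
#>      subtype      p_value stars
#> 1 ER_HER2neg 2.133759e-09  ****
#> 2    HER2pos 7.491521e-07  ****
#> 3       TNBC 7.397974e-08  ****

survival_by_subtype(meta, groups)$TNBC$hazard_ratio$hr
#> [1] 0.3985497
```

Cytolytic activity is higher in TIL-high tumors in every subtype, and
TIL-high TNBC shows the configured survival benefit (estimated hazard
ratio 0.40 against a configured 0.5 at n = 60).
An end-to-end orchestration over files (`run_pipeline()` /
`inst/scripts/tilquant.R`) writes all stage tables plus a JSON run report.

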