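---
title: "Scoring intratumoral TILs from bulk transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring intratumoral TILs from bulk transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilquant)
```

## The problem and the model

Intratumoral tumor-infiltrating lymphocytes — lymphocytes in direct contact
with cancer cells — are too sparse for reliable pathological counting, but
they leave a transcriptional footprint in bulk RNA-seq of tumor-cell-rich
samples. `tilquant` turns that footprint into a per-sample **TIL score** and
runs the downstream association analyses (immune activity, proliferation,
chemotherapy response, survival) on the TIL-high/TIL-low dichotomy.

The causal picture the package assumes is a linear mixture: a bulk sample is
a weighted sum of cell-type expression profiles,

$$x_{gs} = \log_2\!\Big(1 + \sum_c f_{cs}\, p_{cg}\,\eta_{gs}\Big),$$

with cell-type fractions $f_{cs}$ on the simplex, non-negative linear-scale
reference profiles $p_{cg}$, and multiplicative log-normal noise
$\eta_{gs}$. The cancer-cell fraction dominates (median $\ge 0.6$),
mirroring the tumor-cellularity inclusion criteria of the public cohorts
this style of analysis is applied to — which is also what licenses reading
the lymphocyte signal as *intratumoral*.

## Single-sample enrichment scoring

Cell types are scored per sample by a rank-based running sum. Within one
sample, genes are ranked by expression (average ranks for ties, highest
expression = rank $n$). Walking genes in decreasing rank order, a signature
$S$ accumulates

$$\mathrm{score}(S) = \sum_{i=1}^{n} \big[ P^w_{\mathrm{in}}(i) -
P_{\mathrm{out}}(i) \big],$$

where $P^w_{\mathrm{in}}$ weights in-set genes by $\mathrm{rank}^{\alpha}$
(normalized to 1) and $P_{\mathrm{out}}$ is the uniform ECDF of out-of-set
genes. Choices that matter:

* **$\alpha = 0.25$** (default, exposed in `scoring_config()`): the
  conventional weight for this statistic; $\alpha = 0$ gives the unweighted
  rank-sum form used in several hand-checkable tests.
* **Multiple signatures per type** are averaged (the packaged panel carries
  3 signatures × 5 genes per type), mirroring how enrichment-based
  deconvolution tools average several independently derived signatures.
* **Calibration**: raw running-sum scores live on an arbitrary scale, so
  each cell type is min–max calibrated to $[0,1]$ over the cohort. This is
  *cohort-relative*: calibrated scores are not comparable across cohorts,
  and the score matrix records its provenance (estimator, $\alpha$,
  $\kappa$) for that reason.
* **Spillover compensation** (default $\kappa = 0.5$): closely related
  lymphocyte populations co-vary, and their rank-based scores bleed into
  each other. Observed scores are modeled as
  $S_{\mathrm{obs}} = S_{\mathrm{true}}(I + \kappa(K - I))$ with a packaged
  synthetic spill matrix $K$ (unit diagonal, constant level inside the
  lymphocyte block); the linear system is solved and negative solutions are
  clamped at 0. The compensation-plus-clamp measurably denoises subset
  scores on simulated cohorts (composite recovery rises from roughly 0.8 to
  above 0.9); $\kappa = 0$ disables it.
* **Intersection semantics**: signature genes absent from the matrix are
  dropped, never imputed as zeros; cell types whose signatures vanish are
  dropped with a warning.

A deliberately simple **marker-mean estimator** (mean signature-gene log
expression) ships alongside, so the estimator-concordance analysis always
has at least two candidates to rank. On synthetic cohorts the marker-mean
candidate — which uses the very same curated signature genes — is
statistically efficient and can out-rank the enrichment-based candidate in
the concordance row-means. The package therefore asserts the *mechanics* of
selection (Spearman matrix, argmax of row means, lexicographic ties) rather
than which estimator wins; on real data, where signatures are imperfect and
normalization varies, rank-based scoring is the established choice.

## The TIL score and the median split

The TIL score is the sum of 19 lymphocyte cell-type scores (CD4 T cells and
its memory/naive/Tcm/Tem subsets, CD8 T cells and its naive/Tem/Tcm
subsets, Tregs, Th1, Th2, B cells with pro-/naive/memory/class-switched
subsets, NK, NKT). `compute_til_score()` refuses any score matrix missing
one of them. The display value is $\log_2(\mathrm{score} + \varepsilon)$
with $\varepsilon = 10^{-3}$, a guard for exact-zero sums whose particular
value does not affect any downstream grouping.

Groups are formed **within subtype** at the median, with the convention
*score ≥ median → high*. This is the only convention consistent with odd-n
splits like 91/90 (181 samples) or 78/77 (155): the sample sitting exactly
at the median joins the high group. The split commutes with any strictly
monotone transform, so raw-versus-log2 is immaterial except under heavy
ties, which trigger a warning at >20% ties at the median.

## Two-class GSEA

The GSEA stage is self-contained: signal-to-noise ratio
$(\mu_h - \mu_l)/(\sigma_h + \sigma_l)$ with per-group floors
$\sigma \ge \max(0.2\,|\mu|,\, 0.2)$, descending order with gene-name
tiebreak; weighted-KS enrichment score (weight exponent $p = 1$; exact ties
between the positive and negative extreme resolve to the positive side);
phenotype permutation when both groups have ≥ 7 samples, otherwise gene-set
permutation with a warning; NES by same-sign permutation means;
ratio-of-tails FDR q, clipped to 1 and made monotone non-decreasing in
ranked |NES| within each side; significance at q < 0.25. Set sizes are
filtered to [5, 500] after intersection with the gene universe. Permutation
count and seed are recorded in every result row.

Phenotype permutation preserves gene–gene correlation under the null. For
strongly co-expressed immune sets this widens the null ES distribution —
truly enriched but internally correlated sets can carry moderate q-values.
That is intended behavior, not a defect; it is why the permutation type is
the default for the large groups this pipeline targets.

## Outcome statistics

* **CYT** $= \sqrt{(\mathrm{GZMA} + \delta)(\mathrm{PRF1} + \delta)}$ on the
  linear scale ($\delta = 0.01$), after undoing the $\log_2(1+x)$ storage
  transform.
* Two-group comparisons use the two-sample Wilcoxon rank-sum test (exact
  for small tie-free samples, normal approximation with tie and continuity
  correction otherwise). Multi-group comparisons (grade) use tie-corrected
  Kruskal–Wallis. Contingency comparisons (pCR) use the two-sided Fisher
  exact test with the sample odds ratio $ad/bc$. No multiplicity correction
  is applied across the comparison battery; significance stars follow the
  conventional banding (\*≤0.05 … \*\*\*\*≤0.0001).
* Survival: Kaplan–Meier product-limit curves, Mantel–Haenszel log-rank
  $\chi^2$, and a hazard ratio from a single-binary-covariate
  proportional-hazards partial likelihood with Breslow tie handling
  (high vs low; HR < 1 means TIL-high is protective). With zero events in
  one group the partial likelihood is monotone and the HR is reported as
  0/∞ with a `monotone_likelihood` flag rather than a diverging fit.
  These standard estimators are computed through the `survival` package;
  the test suite checks them against independent hand/product-limit and
  enumeration oracles.

## What the synthetic generator emulates

`sim_config()` defaults define the study conditions:

| Parameter | Default | Emulates |
|---|---|---|
| `n_per_subtype` | 100/60/60 | desk-scale cohort with ER+/HER2− the largest subtype |
| `lymph_alpha` | 4/8/14 | lymphocyte mass ordered TNBC > HER2+ > ER+/HER2− |
| `til_dispersion` | 0.8 | wide, roughly bell-shaped log2 TIL spread across tumors |
| `cancer_alpha` | 60 | dominant cancer fraction (median ≈ 0.78) |
| `noise_sd` / `sample_scale_sd` | 0.3 / 0.15 | gene-level biological+technical noise; residual per-sample normalization wobble |
| `pcr_log_odds` | 1 per SD of TIL | TIL-linked chemotherapy response |
| `hazard_ratio` | 1 / 0.5 / 0.5 | survival benefit of TIL-high in HER2+ and TNBC only |
| `grade_til_strength` | 1.5 | TIL-linked Nottingham grade in ER+/HER2− only |
| `til_mutation_rho` | 0.5 | TIL-correlated mutation metrics in ER+/HER2− only (Gaussian copula) |
| `censoring_rate` | 0.3 | independent uniform administrative censoring |

Design points worth stating explicitly:

* **Marker genes are lineage-specific.** Signature genes sit near
  `sig_expr = 10` in their owning type and at a low leak level (0.02–0.1)
  everywhere else; non-signature genes share a moderate baseline. Without
  that specificity — the very property that makes a gene a marker — no
  deconvolution could resolve lymphocyte fractions of a few percent.
  GZMA and PRF1 are expressed across the cytotoxic compartment (CD8 T,
  CD8 Tem, NK, NKT), which is the premise of the CYT score.
* **TIL overdispersion.** A per-sample log-normal multiplier on the
  lymphocyte Dirichlet mass makes total infiltration vary widely *and*
  co-vary with every lymphocyte subset. A plain per-subtype Dirichlet
  would pin total TILs to a narrow band (CV ≈ 0.25 in TNBC) and decouple
  cytotoxic gene expression from the TIL group — neither matches real
  cohorts.
* **Survival and censoring.** Event times are exponential with the
  TIL-group hazard; the censoring horizon is solved numerically so that the
  expected censored fraction equals `censoring_rate` under the baseline
  hazard. The pCR intercept and baseline hazard are deliberately shared
  across subtypes so that pooled null-calibration experiments are free of
  subtype confounding.
* **What it does not emulate:** real gene-level expression distributions,
  platform/batch structure, subtype-specific baseline outcome differences,
  correlated signature errors, or imperfect signature curation. Passing
  recovery tests on these cohorts shows the estimators are correct under
  the mixture model, not that they reproduce any specific real cohort's
  numbers — cohort-relative calibration alone precludes that.

## Numerical choices and degenerate inputs

Ties in ranks use average ranks; the enrichment-score extreme resolves ties
toward the positive deviation within a $10^{-12}$ relative tolerance
(running sums are accumulated in extended precision, so exact mathematical
ties can differ in the last bit). All-constant samples are rejected rather
than silently scored. Dichotomization warns on heavy median ties and
errors on subtypes with fewer than 2 samples. The spillover system refuses
near-singular matrices ($|\det| < 10^{-12}$). Fisher tests refuse zero
margins, but the pCR battery reports `p = 1` with a flag for strata with no
events in either group (a well-defined "no signal" answer rather than an
error mid-pipeline).

## Problem sizes used in validation

The packaged validation suite simulates 220-sample cohorts (100/60/60) with
500-gene panels; calibration experiments use 200 replicates at 60 samples,
and hazard-ratio coverage uses 100 replicates at 300 samples. These sizes
were chosen so the full suite runs on a laptop in minutes while leaving
Monte-Carlo bands (3 binomial SEs around nominal size; ≥ 90% CI coverage)
tight enough to detect real miscalibration.

## Known limitations

* Per-type subset scores have an intrinsic resolution ceiling: a
  within-sample rank statistic compresses differences between co-varying
  subsets, so closely related lymphocyte types recover at Spearman
  ≈ 0.6–0.8 while the 19-type composite recovers above 0.9. The composite
  is the quantity the analysis rests on.
* Calibrated scores are cohort-relative; absolute comparability across
  cohorts is explicitly not claimed.
* The survival stage is a single-covariate contrast; no multivariable
  adjustment, time-dependent effects, or competing risks.
* Mutation metrics (ITH, HRD, mutation rates, neoantigen counts) are
  consumed as precomputed columns — their upstream computation is out of
  scope, and the simulated stand-ins only reproduce the correlation
  structure, not the marginals, of the real quantities.
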