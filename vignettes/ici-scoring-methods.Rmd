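---
title: "Methods behind the ICI scoring pipeline"
author: "icikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the ICI scoring pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

`icikit` treats a bulk tumor transcriptome as a mixture: the expression of
gene $g$ in sample $s$ is approximately $\sum_c S_{gc} w_{cs}$, where $S$ is
a genes × cell-types signature matrix and $w_{\cdot s}$ the sample's
cell-type proportions on the unit simplex. Everything downstream is built on
that view:

* **Deconvolution** estimates $w_{\cdot s}$ by non-negative least squares
  (NNLS) over the genes shared between the data and the signature, then
  renormalizes to the simplex. NNLS is a transparent estimator of the same
  linear mixture model that reference-based deconvolution tools fit; its
  accuracy here is validated against planted ground truth (mean absolute
  error ≈ 0.015 at the default noise level), and precomputed fraction tables
  from any external tool can be dropped in via `FractionMatrix()`. The
  per-sample permutation p-value shuffles the sample's gene labels and asks
  how often a refit correlates with the data as well as the real fit.
* **ICI clusters** come from Monti-style consensus clustering: repeatedly
  subsample 80 % of the samples, cluster with k-means (or Ward hclust), and
  record for each pair the fraction of co-sampled runs in which it
  co-clustered. The number of clusters is the one minimizing the proportion
  of ambiguous clustering (PAC, the share of consensus entries in
  (0.1, 0.9)); ties go to the smaller $k$, and a minimum PAC above 0.5 is
  flagged as "no structure". The consensus-CDF area and its relative change
  are reported for inspection. k-means is the default base clusterer because
  it is fast and deterministic under seeding; pairs never co-sampled are NA,
  never silently zero.
* **Signature genes** are one-vs-rest moderated-t DEGs between the ICI
  clusters, at $|\log_2 \mathrm{FC}| > 1$ and raw $p < 0.05$ (the
  fold-change rule is read on the log2 scale — on the natural scale
  "absolute fold change > 1" excludes nothing). The union over contrasts is
  the default (a gene may mark any one cluster); intersection is available.
  Unadjusted p at 0.05 mirrors the conventional workflow this pipeline
  follows; BH-adjusted selection is a flag away.
* **The score.** The DEG expression is consensus-clustered into two gene
  clusters; each DEG joins side A or B according to the sign of its mean
  difference between the two clusters. Each side is summarized by the first
  principal component of its standardized expression, and the ICI score is
  $\sum \mathrm{PC1}_A - \sum \mathrm{PC1}_B$ (one PC1 per side by default;
  multiple sets per side are accepted). PC1 signs are fixed by positive
  correlation with the side's mean standardized expression, otherwise the
  eigenvector sign ambiguity would silently flip scores between runs.
* **Stratification** uses the maximally selected log-rank cutoff: every
  observed score value leaving both groups at least 10 % of the cohort is a
  candidate, the split is at `score > cutoff` (ties low), and the chosen
  cutoff maximizes the two-group log-rank chi-square. Because the maximum is
  selected, its naive p-value is optimistic; the selection-adjusted p
  compares the maximal statistic against a permutation null (scores permuted
  against survival, the scan repeated). Permutation was preferred over the
  analytic maximally-selected-rank bound because it makes no additional
  approximations and is seedable.

## Boruta-style reduction

The optional dimensionality-reduction step appends a shuffled "shadow" copy
of every signature gene, fits a random forest classifying the gene-cluster
label (the response most faithful to how the signature was constructed), and
counts a hit whenever a real gene's impurity importance beats the best
shadow. After $n$ iterations, genes outside the two-sided binomial($n$, 0.5)
band at $\alpha = 0.01$ are confirmed or rejected; tentatives are excluded
from the confirmed list. Reduction runs after the A/B split, per side, and a
side that would shrink below two genes keeps its full set — the score needs
a PC1 per side. Note the all-relevant character of this procedure: with very
small cohorts, features spuriously correlated with the response in-sample
can be confirmed; that is a property of the method, not a defect of the
implementation.

## Score orientation

Consensus cluster labels are arbitrary (we relabel by decreasing size for
determinism), so which gene cluster is called "A" — and hence the global
sign of PC1A − PC1B — is arbitrary too. Published analyses fix the sign
implicitly by inspecting which group is immune-activated. `scoreCohort()`
makes that explicit: an optional `orientBy` covariate (any per-sample
immune-content measure, e.g. an immune ssGSEA score or the mean expression
of immune marker genes) flips the A/B designation when the score
anti-correlates with it, so "high ICI" always means immune-rich. Without
`orientBy` the size-based labeling is kept as is.

# The synthetic cohort generator

`simulateCohort()` generates exactly the structure the pipeline assumes,
with planted truth for every stage: a signature matrix with disjoint marker
blocks (cell type 1 acting as the tumor compartment, the rest immune;
markers elevated `markerFold`-fold), three subtypes whose cell-type
proportions are Dirichlet draws with subtype-specific concentrations
(subtype B immune-hot, C tumor-heavy/cold, A intermediate), expression =
signature · proportions under multiplicative log-normal noise, and
exponential survival with subtype hazards under independent exponential
censoring (the simplest non-informative censoring).

Defaults were fixed once, for realistic separation and comfortable
downstream recovery: n = 300 samples, 1000 genes, 5 cell types, 50 markers
per type, marker fold 12, noise sd 0.3, hazards (1, 0.5, 2) × 10⁻³ per day
for A/B/C, censoring rate 5 × 10⁻⁴. The marker fold is higher than the
mixture-recovery stages alone would need because the DEG stage works on the
log2 scale: a fold of 12 puts the between-cluster contrast of marker genes
just comfortably past the |log2 FC| > 1 threshold after mixing, which is the
binding constraint. The Dirichlet concentrations (totals ≈ 150) keep
within-subtype spread well below between-subtype separation, so consensus
clustering recovers the subtypes with ARI ≥ 0.94 across seeds.

What the generator does *not* emulate: real cohorts have correlated genes
beyond cell-type co-regulation, heavier-tailed expression noise, batch
structure, non-proportional hazards and informative censoring. Passing the
recovery suites therefore demonstrates correctness of the machinery under
the model's own assumptions, not performance guarantees on any particular
cancer cohort.

`simulateMaf()` plants a log-linear TMB–score link (Poisson counts with
mean $\exp(\log 10 + 0.5 z(\mathrm{score}))$) and three catalog genes with
5-fold mutation odds in high-score samples, giving the contingency stage a
known signal. Records carry a random non-silent class over a 200-gene
catalog so that exact duplicates (removed by contract) are vanishingly rare
and the per-sample count keeps its Poisson mean. `simulateScMetadata()`
plants three low-quality subpopulations, each violating exactly one QC rule,
so removal counts can be checked by construction.

# Numerical choices and edge cases

* **Cohort merging** restricts to shared genes, transforms to
  log2(TPM + 1), and z-scores each gene within each cohort before
  concatenation. No named batch method is assumed; within-cohort
  standardization is the simplest transform that removes cohort-level
  location/scale differences and feeds the rank- and PCA-based stages
  downstream. Genes with zero within-cohort variance are dropped with a
  message. Merge-first is the default ordering; fractions can equally be
  estimated per cohort before merging by calling the stages directly.
* **Moderated t.** The prior $(d_0, s_0^2)$ is moment-matched on the log
  sample variances (Newton inversion of the trigamma function). When the
  observed spread of log variances is at or below chi-square sampling noise,
  $d_0 = \infty$ and the prior collapses to the geometric mean of the
  observed variances — making identical sample variances an exact fixed
  point of the shrinkage. `shrink = FALSE` gives the ordinary pooled t.
  Zero-variance genes with zero fold change get p = 1 with a message.
* **ssGSEA** ranks within sample (average ranks on ties; weight
  rank^0.25 by default) and sums the in-set minus out-of-set ECDF
  difference; a set covering all genes scores exactly 0. Purity calibration
  coefficients are platform-specific and must be supplied; without them the
  purity column is NA rather than silently wrong.
* **GSEA** uses a gene-label permutation null so that arbitrary externally
  supplied rankings are testable; NES normalizes by the same-sign null mean.
* **TMB** is the raw non-silent record count (missense, nonsense,
  frameshift/in-frame indels, splice site, nonstop, translation start
  site); the class list is an argument, and per-megabase scaling is left to
  the caller since capture sizes vary.
* **Yates correction is on** for the 2×2 contingency tests: the printed
  tables this stage reproduces are consistent with the corrected statistic
  and not with the uncorrected one. `correct = FALSE` is available.
* **Ties policy:** samples exactly at the score cutoff or the median
  (risk and TMB splits) go to the *low* group, consistently.
* **Degenerate survival** (no events, or a single event time) makes the
  cutoff search fall back to the median with a warning.
* **QC boundaries are inclusive on the keep side** (exactly 200 genes,
  15 % mitochondrial counts, novelty 0.8 are kept) since the filters are
  phrased as removing cells strictly beyond the thresholds. HVG selection
  standardizes log-scale variances within 20 equal-occupancy mean bins, the
  usual guard against the mean–variance trend.

# Problem sizes used in validation

The shipped test-and-validation suites use cohorts of 100–300 samples and
1000 genes, 100–250 consensus resamples, 25–50 pipeline seeds, 100–200
simulation replicates for the calibration checks, and 99–500 permutations
where permutation nulls are tested — sizes at which every recovery margin
above holds with room to spare while the whole suite stays quick to run.
Production analyses can raise `reps` (the conventional 1000 iterations) and
permutation counts freely; results stabilize well below those values on
data of this scale.

# Known limitations

* NNLS deconvolution ignores the quantile normalization and ν-SVR
  machinery of canonical reference tools; absolute-mode scores are out of
  scope. Use the `FractionMatrix()` hook for canonical output.
* One-factor designs only in the DE stage: no covariates, no voom weights.
* No competing risks, time-varying covariates or frailty in the survival
  stage; the time-dependent AUC is the cumulative/dynamic IPCW estimator.
* Gene-set databases are not bundled; supply GMT files.
* Single-cell support stops at QC and HVG selection by design — clustering,
  embedding and trajectory analysis belong to dedicated toolkits.
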