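# icikit

Immune cell infiltration (ICI) scoring for bulk tumor transcriptomes.

Tumors with the same diagnosis differ widely in how strongly immune cells
infiltrate them, and that difference carries prognostic and immunotherapy
information. `icikit` implements an end-to-end scoring pipeline that turns a
genes × samples expression matrix plus survival data into a per-sample ICI
score and a high/low stratification:

1. **Deconvolution** — per-sample immune cell fractions by non-negative least
   squares against a cell-type signature matrix (any genes × cell-types TSV;
   externally computed fraction tables are accepted too), plus ssGSEA-based
   stromal/immune microenvironment scores.
2. **ICI clusters** — Monti-style resampled consensus clustering of the
   fraction profiles; the number of clusters is chosen by the proportion of
   ambiguous clustering (PAC).
3. **Signature genes** — moderated-t (empirical-Bayes) one-vs-rest
   differential expression between ICI clusters, thresholded at
   |log2 FC| > 1 and p < 0.05.
4. **Gene clusters and the score** — consensus clustering of the DEG
   expression into two gene clusters A/B; each DEG is assigned to the side it
   is positively associated with; an optional Boruta-style shadow-feature
   random-forest filter reduces each side; each sample is scored by the first
   principal component of each side, and

   ICI score = PC1(A) − PC1(B)

5. **Survival stratification** — samples split at the maximally selected
   log-rank cutoff (selection-adjusted significance by permutation), plus Cox
   risk models with time-dependent AUC.
6. **Mutation integration** — tumor mutational burden (non-silent MAF record
   counts), per-gene high/low contingency tables with Yates-corrected
   chi-square tests, Spearman TMB–score association, and TMB × ICI survival
   strata.
7. **Enrichment and single-cell QC** — hypergeometric over-representation,
   GSEA with a gene-label permutation null, the standard single-cell filters
   (≥ 200 detected genes, ≤ 15 % mitochondrial counts, novelty ≥ 0.8) and
   top-2000 highly variable gene selection.

A synthetic cohort generator (`simulateCohort`, `simulateMaf`,
`simulateScMetadata`) plants known immune subtypes, subtype-linked survival
and score-linked mutation burden, so every stage can be validated against
ground truth.

## Worked example

```r
library(icikit)

co <- simulateCohort(nSamples = 300, seed = 1)      # planted subtypes A/B/C
imm <- colMeans(log2(exprValues(co$expression)[co$immuneMarkers, ] + 1))
res <- scoreCohort(co$expression, co$clinical, co$signature,
                   reps = 100, orientBy = imm, seed = 1)

res$scores
#> ICIScores: 300 samples, cutoff = -5.976 (high: 194, low: 106)
res$logrank$p
#> [1] 1.747303e-16
adjustedRandIndex(clusterLabels(res$iciClusters), co$truthSubtype)
#> [1] 0.9899832
```

The consensus clusters recover the three planted immune subtypes almost
perfectly (adjusted Rand index 0.99), and the high-ICI group — oriented
toward the immune-rich subtype — separates survival sharply (log-rank
p ≈ 2e-16), as planted: the immune-hot subtype was simulated with half the
hazard of the cold one.

Mutation integration on the same cohort:

```r
maf <- simulateMaf(names(iciScores(res$scores)), iciScores(res$scores),
                   tmbSlope = 0.5, seed = 2)
tmb <- computeTmb(maf, names(iciScores(res$scores)))
tmbScoreAssociation(tmb, iciScores(res$scores))
#> $rho 0.797   $p 2.98e-67
head(mutatedGeneTable(maf, scoreGroups(res$scores)), 3)
#>     gene high_wild high_mut high_pct low_wild low_mut low_pct     chi2        p
#> 1 MUT002       146       48    24.74      103       3    2.83 21.80    3.0e-06
#> 2 MUT003       152       42    21.65      101       5    4.72 13.62    2.2e-04
#> 3 MUT001       152       42    21.65       99       7    6.60 10.28    1.3e-03
```

`runPipeline(config, outdir)` drives the same chain from TSV/MAF files on
disk (config as a list or YAML) and writes one TSV per stage plus a run log.

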