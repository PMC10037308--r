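Package: icikit
Title: Immune Cell Infiltration Scoring for Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the tumor immune microenvironment from bulk expression
    data and builds a per-sample immune cell infiltration (ICI) score. The
    pipeline estimates immune cell fractions by non-negative least squares
    against a signature matrix, derives ICI clusters by resampled (Monti-style)
    consensus clustering of the fraction profiles, extracts signature genes by
    moderated-t differential expression between clusters, reduces them with a
    shadow-feature (Boruta-style) random-forest filter, and scores each sample
    as the difference of the first principal components of the two signature
    gene sets. Samples are stratified at a maximally selected log-rank cutoff,
    and the score is integrated with tumor mutational burden via Yates-corrected
    contingency tests and Spearman association. Includes single-sample gene-set
    enrichment (ssGSEA), GSEA and hypergeometric over-representation, Cox risk
    models with time-dependent AUC, single-cell QC filters, and a synthetic
    cohort generator with planted subtypes, survival and mutation structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    pracma,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
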