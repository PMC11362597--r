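Package: apmsEnrich
Title: Differential Enrichment and Credibility Scoring for AP-MS Interactomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end analysis pipeline for affinity-purification
    mass-spectrometry (AP-MS) interactome discovery from label-free
    quantification (MaxLFQ) protein tables. Covers detection-based
    filtering, missing-not-at-random imputation from a left-shifted
    Gaussian, variance-stabilizing per-sample calibration,
    empirical-Bayes moderated t-statistics with Benjamini-Hochberg
    control for bait-versus-control enrichment, a detection-rate and
    fold-change based credibility classification of candidates against
    co-immunoprecipitation data, paired comparison of GTPase
    nucleotide-loading states, a quality-control battery (PCA, Pearson
    correlation, detection counts, overlap partition, hierarchical
    clustering), and a synthetic AP-MS data generator with ground truth
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    nortest,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, QualityControl
RoxygenNote: 7.3.3
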