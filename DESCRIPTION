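Package: ICIwindow
Title: Biomarker Discovery for Immune-Checkpoint-Inhibitor Window Trials
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Tools for on-treatment biomarker discovery in window-of-opportunity
        immune-checkpoint-inhibitor (ICI) trials of gastro-esophageal cancer.
        Derives and scores an ICI-responsive T/NK inflammation signature from
        paired pre-/on-treatment tumor transcriptomes using median-of-ratios
        normalization and empirical-Bayes moderated paired tests; runs preranked
        gene-set enrichment with a permutation null; estimates bulk tumor cell
        composition by reference-based non-negative least-squares deconvolution
        with a pseudobulk ground-truth benchmark and extracts tumor monocyte
        content (TMC); computes genomic biomarkers (tumor mutational burden,
        microsatellite instability, copy-number classes); and stratifies
        survival outcomes by TMC and TMB via Kaplan-Meier, log-rank and Cox
        analyses. A synthetic-cohort generator reproduces the statistical
        structure these analyses assume, so every stage can be exercised
        against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival,
    pracma,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, SingleCell, Survival,
    ImmunoOncology, Software
RoxygenNote: 7.3.3
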