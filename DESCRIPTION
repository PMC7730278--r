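Package: invresist
Title: Dose-Response and Transcriptome Trend Analysis for Gradual Inverse
    Drug Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for isogenic cancer cell-line series that
    gradually acquire resistance to one drug together with collateral
    sensitivity to another ("inverse resistance"). Provides cytotoxicity
    plate processing for the alamarBlue assay (two-wavelength percent
    reduction, viability curves, interpolation-based IC50/pIC50,
    resistance and sensitivity indices, consecutive fold changes, and two
    statistical curve comparisons: a random-slope mixed model and a pooled
    t-test on pIC50); ordered-series differential expression from RNA-seq
    count matrices (CPM low-expression filter, log-CPM transformation,
    empirical-Bayes moderated t-statistics, Benjamini-Hochberg FDR); kinetic
    trend classification of genes across the ordered contrasts into five
    patterns with scaffold-gene selection, shared-DEG matrices, PCA and
    hierarchical clustering; and scaffold protein-protein interaction
    network construction with hub detection and hypergeometric gene-set
    enrichment. A synthetic-data module generates plates, negative-binomial
    count matrices with planted trend structure, and scored edge lists with
    planted hubs, so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    edgeR,
    lme4,
    lmerTest,
    igraph,
    ape,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
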