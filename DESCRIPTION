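Package: progmarker
Title: Progressive Disease-Marker Discovery from Label-Free Quantitative Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for label-free quantitative (LFQ)
    proteomics of disease-progression cohorts, modelled on MaxQuant/Perseus
    conventions. Reads MaxQuant-style proteinGroups tables, filters protein
    groups, log2-transforms and imputes missing-not-at-random zeros by Gaussian
    down-shift, runs sample-level quality control (inter-patient Pearson
    correlation, outlier flagging, housekeeping stability), principal component
    analysis and hierarchical clustering, per-protein one-way ANOVA with
    Benjamini-Hochberg control, empirical-Bayes moderated t statistics, and an
    S0-modified volcano significance rule. Its core is a disease-marker
    procedure for ordered cohorts (benign endometrium, endometriosis,
    carcinoma): one-sided moderated tests per adjacent transition with a
    conservatively inflated control variance, right-boundary estimation of the
    true-null proportion, a two-group local false discovery rate model giving a
    posterior probability of elevation, and classification of proteins into
    progressive expression patterns. A seeded synthetic-data generator with
    intensity-dependent dropout and known ground truth makes every stage
    testable without external data. Signature concordance, signature-based
    cohort discrimination and hypergeometric over-representation analysis
    against user-supplied gene sets complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
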