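Package: scaldnet
Title: Integrated Metabolome-Transcriptome Network Analysis of Delayed
    Chilling Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating time-course metabolomic and
    transcriptomic profiles of cold-stored fruit peel to dissect delayed
    chilling injuries such as superficial scald of apple. Implements
    multi-block partial least squares discriminant analysis (MBPLS-DA)
    with a super-score layer, block-rescaled Variable Importance in
    Projection (VIP) scoring and selection, PCA-smoothed k-means
    summarization of gene expression, windowed Pearson correlation
    networks linking gene clusters to anchor metabolites during
    pre-symptomatic and symptomatic storage phases, first-neighbor
    subnetwork extraction with per-gene refinement, and Fisher-exact
    over-representation analysis of functional bins. A synthetic-data
    generator reproduces the study design (three postharvest treatments,
    eight storage durations, replicated observations) with planted marker
    metabolites and correlated gene clusters so the whole pipeline is
    testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
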