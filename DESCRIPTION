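Package: dualomics
Title: Integrative Gut Microbiome and Serum Metabolome Analysis for
    Gestational Diabetes Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative dual-omics toolkit for case-control pregnancy
    cohorts profiled by shotgun metagenomics (MetaPhlAn-style relative
    abundances) and untargeted serum metabolomics. Implements rank-based
    differential abundance testing with Benjamini-Hochberg false-discovery
    control, alpha/beta diversity and ANOSIM, coverage-normalized metabolic
    pathway activity scores, Spearman co-occurrence networks with a
    subsample-bootstrap comparison of graph metrics between groups, greedy
    log-ratio balance selection with cross-validation against glycemic
    outcomes, sparse partial least squares integration of omics blocks, and
    Shapley-value attribution of species to pathway signals via random-forest
    regression. Ships a synthetic cohort generator with planted, recoverable
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
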