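Package: limbtempo
Title: Time-Course Transcriptome Analysis of Murine Limb Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk expression time courses of developing
    mouse limbs profiled against whole-embryo controls at five embryonic
    stages (E9.5-E13.5). Provides quantile normalization and median-polish
    summarization, empirical-Bayes moderated t-statistics with
    Benjamini-Hochberg adjustment, combinatorial classification of temporal
    up-regulation profiles into 31 pattern classes, delay-adjusted calling of
    forelimb- and hindlimb-identity genes, hypergeometric gene-set
    over-representation with fold enrichment, and diagnostic analyses
    (per-gene z-normalization, Wilcoxon rank-sum false-negative screens,
    low-expression flagging). A seeded synthetic-data generator emulating the
    study design makes every stage testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
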