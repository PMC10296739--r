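Package: mirTally
Title: Integrated miRNA-mRNA Differential Expression and Combinatorial
    Target-Count Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrated analysis of paired microRNA and mRNA
    expression studies with a two-factor (age x exposure) design, as used in
    prenatal-alcohol-exposure models. Implements MAS5-style detection calls
    and the expression/species/uniqueness probe-filtering funnel, RMA-style
    quantile normalization and median-polish summarization, per-feature
    unbalanced two-factor ANOVA with Storey q-values, and the combinatorial
    target-count statistic: tallying how many distinct differentially
    expressed miRNAs target each gene, relating that count to mRNA fold
    change, and contrasting it against an expression-matched list of
    non-differentially expressed miRNAs via residual fold changes. Includes
    parsers for TargetScan- and miRWalk-style target-prediction files, a
    principal-component-ordered co-expression view of the differentially
    expressed miRNAs, and a seeded synthetic-data generator with planted
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
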