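Package: efsbench
Title: Benchmarking Eliminative Feature Selection for Radiomic Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark harness for eliminative feature selection (EFS) on
    wide radiomic feature tables. Provides a linear-discriminant wrapper
    evaluator scored by balanced accuracy, seven selector families (random
    selection, highly-correlated-feature removal, recursive feature
    elimination with and without cross-validation, sparse discriminant
    analysis via elastic-net penalised optimal scoring, genetic-algorithm
    subset search, and dual-phase combinations), a prefilter that removes
    strongly anti-correlated feature pairs, a seeded generator of correlated
    synthetic feature tables with planted informative subsets, and a
    repetition harness producing balanced-accuracy distributions and
    selection-frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
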