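Package: coordinatr
Title: Coordination Analysis of Gene Expression Between Two Groups
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genes whose transcriptome-wide correlation profile
    decorrelates between a reference and a condition group of expression
    samples. Implements high-expression filtering, within-group pairwise
    Pearson correlation, per-gene transcriptome correlation profiles, a
    composite correlation statistic (Pc) comparing the two groups' profiles,
    extraction of correlated gene sets, local hypergeometric
    over-representation against GMT annotations, and Function Retention /
    Function Acquisition indices. Ships a Gaussian-copula negative-binomial
    simulator that plants block co-expression modules and rewired genes so
    the whole pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pheatmap
Config/testthat/edition: 3
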