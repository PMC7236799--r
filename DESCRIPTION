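Package: rifnet
Title: Regulatory Impact Factor Analysis of Two-Condition Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Differential-network analysis for two-condition bulk
    transcriptomes. Scores every candidate regulator by the regulatory
    impact factor statistics RIF1 and RIF2, which measure how strongly a
    gene's co-expression with the differentially expressed (DE) target set
    changes between a treated and a control condition, independently of the
    gene's own differential expression. Provides the upstream DE screen, the
    phenotypic-impact-factor (PIF) times differential-co-expression ranking
    of targets around a focal regulator, hypergeometric enrichment of gene
    sets in the extremes of a ranked list, a synthetic-data generator that
    plants differentially connected regulators with ground-truth labels, and
    a pipeline driver with reproducibility manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
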