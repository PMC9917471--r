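Package: rgstab
Title: Reference-Gene Selection and Expression-Stability Analysis for qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting and validating reference genes for
    real-time quantitative PCR (qPCR) normalisation. Implements RNA-seq
    based candidate screening (fold-change, false-discovery-rate and
    coverage filters plus ANOVA and t-tests on gene counts), quantification
    cycle (Cq) data handling with amplification-efficiency correction, four
    expression-stability estimators (geNorm, NormFinder, BestKeeper and the
    comparative delta-Ct method), and a comprehensive meta-ranking by
    geometric mean of within-method ranks. Includes a seeded simulator for
    Cq tables and negative-binomial count matrices with planted stable and
    unstable genes, and a command-line workflow binding the stages
    together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
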