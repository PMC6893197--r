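Package: modscreen
Title: Mixed-Model GWAS and Variant-Level Gene-Set Enrichment for
    Inbred-Panel Modifier Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative modifier screens across inbred mapping
    panels such as the Drosophila Genetic Reference Panel: strain-level
    phenotype summaries and background-effect ANOVA, per-variant linear
    mixed-model association against a centered genetic relatedness matrix,
    window-based variant-to-gene assignment with feature-priority
    tie-breaking, weighted Kolmogorov-Smirnov gene-set enrichment with a
    permutation null, and Dunnett many-to-one statistics for knockdown
    validation experiments. A synthetic panel generator with planted causal
    structure lets the whole screen be exercised end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mvtnorm
Config/testthat/edition: 3
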