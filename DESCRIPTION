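Package: depcr
Title: Quantifying Primer-Template Interactions with Deconstructed PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative framework for measuring primer-template
    interactions in amplicon PCR. Builds a synthetic design space of
    templates that differ only at three priming-site positions and at a
    short internal recognition sequence, together with the full
    combinatorial set of primer variants. Simulates two amplification
    regimes: deconstructed PCR (DePCR), in which two cycles of linear
    copying preserve the identity of the primer that annealed to each
    source template, and standard exponential PCR, in which primers
    anneal to amplicon copies and scramble that signal. Classifies reads
    into primer-by-template interaction counts by exact matching,
    rarefies the resulting count matrices, and computes Ideal Template
    and Primer Scores, mismatch ratios, positional error-rate profiles,
    Bray-Curtis dissimilarities and ordinations, with Welch t and
    ANOVA/Tukey group comparisons for reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    optparse
Config/testthat/edition: 3
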