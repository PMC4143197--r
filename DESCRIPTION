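Package: regarch
Title: Structural-Feature Models of Cis-Regulatory Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the cis-regulatory architecture shared by the regulatory
    regions of co-expressed genes. Regulatory regions anchored at the
    transcription start site are scanned with position-specific scoring
    matrices whose hit thresholds are calibrated empirically against random
    background regions. Motif occurrences are summarised as binary structural
    features in four classes (distance from the TSS in 100-bp bins, pairwise
    spacing, strand orientation, and relative order of up to three motifs).
    Irrelevant features are removed with a fast correlation-based filter built
    on symmetrical uncertainty, surviving features are weighted with a
    Kullback-Leibler relevance metric, and an optimal feature subset is chosen
    by a genetic algorithm under stratified cross-validation. The fitted model
    scores regulatory regions genome-wide and checks feature conservation in
    orthologous regions. A seeded synthetic-data generator plants structural
    grammars in simulated genomes so the whole pipeline can be exercised and
    benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
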