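Package: disphase
Title: Intrinsic Disorder and Liquid-Liquid Phase Separation Proteome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A proteome-scale meta-analysis pipeline for protein intrinsic
    disorder and liquid-liquid phase separation (LLPS). Computes per-protein
    disorder metrics (average disorder score, percentage of predicted
    disordered residues) from per-residue predictor tracks, assigns proteins
    to charge-hydropathy / cumulative-distribution-function (CH-CDF) phase
    space quadrants, calls consensus-disordered residues and quantifies their
    overlap with structural domain annotations, performs hypergeometric set
    enrichment, classifies droplet-driver and droplet-client proteins and
    calls droplet-promoting regions, summarizes protein interaction networks,
    and fits the Box-Cox-transformed polynomial regression linking disorder to
    LLPS propensity. A fully synthetic proteome generator with planted,
    configurable statistical structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
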