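Package: cfsdel
Title: Deletion Hotspots at Common Fragile Sites and the Resolved
    Stalled Fork Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects large-deletion hotspots at common fragile sites from
    cohort structural-variant calls, tests whether deletion breakpoints fall
    between consecutive replication origins (Ini-seq peaks) and TAD
    boundaries, relates deletion and duplication positions within large
    genes to the transcription-dependent double-fork failure model, confirms
    deletions with split RNA-seq junction reads, and derives a resolved
    stalled fork (RSF) biomarker from per-sample hotspot deletion counts via
    piecewise-linear changepoint fitting, with Kaplan-Meier, log-rank and
    Cox proportional-hazards survival association. A synthetic cohort
    generator reproduces the statistical structure the analysis assumes, so
    the full pipeline is testable without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    graphics,
    methods,
    stats,
    survival,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
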