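Package: atacdyn
Title: Time-Course Chromatin Accessibility Dynamics, Expression Modules,
    and Occupancy Integration
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies genomic intervals from multi-condition ATAC-seq time
    courses into open/closed state-transition modules (permanently open,
    open-to-close, close-to-open) with timing submodules anchored on start
    and endpoint reference samples; builds union peak atlases and boolean
    state matrices from per-sample peak calls; categorizes differential
    expression across parallel perturbation systems into common and
    system-specific up/down modules; annotates peaks to genomic features and
    TSS-linked genes; computes hypergeometric gene-set overlaps and
    class-normalized binding occupancy metrics; and ships a seeded
    synthetic-data generator with planted ground truth plus a command-line
    pipeline for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
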