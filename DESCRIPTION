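Package: anatidna
Title: Waterfowl eDNA Metabarcoding: In-Silico PCR, ASV Processing and
    Community Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tribe-targeted waterfowl environmental DNA (eDNA)
    metabarcoding surveys. Implements mismatch-tolerant in-silico PCR for
    IUPAC-degenerate primer pairs against reference sequence sets with
    target-versus-non-target specificity summaries; BLAST-style taxonomic
    assignment of amplicon sequence variants (ASVs) with a lowest-common-rank
    fallback; negative-control based ASV filtering; proportional
    sequencing-depth standardization; and the statistical layer relating
    eDNA-derived relative abundance to visual count surveys: log-log Pearson
    correlations, per-date Kendall concordance, 0-5 day lagged correlations
    and a thresholded correlation network over dated community snapshots. A
    seeded synthetic-data generator emulates migration abundance
    trajectories, visual and checklist surveys, reference sequences with
    embedded primer sites, and overdispersed ASV read tables with negative
    controls, so the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
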