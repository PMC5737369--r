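Package: anchorage
Title: Draft-Genome Anchoring, Variant Summarisation and Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning a fragmented draft plant genome into
    chromosome-scale pseudomolecules and breeder-ready DNA markers.
    Implements k-mer histogram genome-size estimation, two-stage scaffold
    anchoring (genetic-map placement plus synteny with a related reference,
    via collinear gene runs and linear-regression fits), AGP emission and
    coordinate liftover, hard filtering and summarisation of resequencing
    variants with a simplified sequence-ontology effect classifier, and
    design of CAPS, indel, microsatellite (SSR) and PCR-primer markers.
    Ships seeded synthetic-data generators with full truth tables so every
    stage is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
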