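Package: pollensift
Title: Plant Metabarcoding Classification and Surface-Contamination
    Assessment for Insect Gut-Content Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for rbcLa amplicon metabarcoding of insect gut contents
    on long-read (nanopore) data, built around the problem of separating
    dietary plant signal from surface pollen contamination. Provides
    reference-database curation (primer-delimited amplicon extraction,
    quality filtering, dereplication), read quality control, a seeded
    affine-gap local aligner with tabular hit import/export, hit filtering
    with a top-bitscore window, majority-rule lowest-common-ancestor read
    classification, per-sample taxon profiling with taxon-selection and
    genus-collapsing rules, contamination and replicate-detection
    reporting, TaqMan qPCR cycle-threshold summarisation, and a synthetic
    read simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
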