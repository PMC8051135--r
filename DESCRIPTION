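Package: chromstretch
Title: Stretch-Enhancer and Binding-Site Analysis from Chromatin-State Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream regulatory-genomics toolkit for paired-condition
    (progenitor versus differentiated) epigenome studies. Calls enhancers by
    stitching enhancer-state segments from ChromHMM-style chromatin-state
    segmentations, classifies stretch enhancers (> 3 kb) and shared/unique
    enhancer sets by bidirectional overlap, classifies transcription-factor
    binding sites by chromatin-state transitions between conditions, computes
    aggregate signal and PWM motif-density profiles around binding sites, and
    tests stretch-enhancer enrichment near a signature gene set with an
    expression-matched permutation test. Includes a synthetic-data generator
    that plants known structure (signature genes near stretch enhancers,
    promoter-binding expression boosts, class-specific motif instances) so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
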