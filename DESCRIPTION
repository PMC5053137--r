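Package: znsite
Title: Detection, Annotation Correction, Restraint Generation and
    Geometric Validation of Tetrahedral Zinc Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies putative tetrahedral ZnCys(x)His(y) coordination
    complexes in macromolecular coordinate files, corrects their
    SSBOND/LINK annotation ("Cys-cleaning"), emits distance and angle
    restraints in the REFMAC external-restraint dialect, and validates
    site geometry against composition-specific target tables using
    per-feature Z-scores combined into a root-mean-square Z quality
    metric.  A synthetic-site generator builds ideal and distorted
    fixtures (including octahedral decoys and corrupted annotation) so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
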