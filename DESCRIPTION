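Package: wedgemerge
Title: Multi-Crystal Small-Wedge Diffraction Data Merging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for merging many small-wedge (1-30 degree) X-ray
    diffraction datasets collected from microcrystals into one dataset.
    Reads per-wedge unmerged reflection files in an XDS_ASCII-style text
    format, groups wedges by Niggli-reduced unit cell, resolves indexing
    ambiguity (by reference data or an iterative selective-breeding style
    correlation ascent), clusters datasets by intensity correlation or
    unit-cell variation, scales and merges them in batches with an
    XSCALE-style error model and iterative frame and dataset outlier
    rejection, and reports per-shell data-quality statistics (CC1/2,
    CCano, Rmeas, completeness, multiplicity) with an automatic
    CC1/2-based resolution cutoff. A bundled simulator generates wedge
    cohorts with full ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
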