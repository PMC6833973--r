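Package: vsdflex
Title: Sequence-Based Local Flexibility Profiling of Voltage-Sensor Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the intrinsic local flexibility of voltage-sensor
    domain (VSD) segments of voltage-gated ion channels from primary sequence.
    Builds per-column frequency profiles, ranked consensus sequences and
    sequence-logo matrices from family alignments; locates the conserved NxxD
    anchor motif (and its FxxD and C/S-x-x-D variants) and cuts the S3, S3-S4
    and S1-S4 analysis windows; converts segments into smoothed normalized
    B-value profiles, the mean B-factor (mBf) and the 1/mBf flexibility index
    with cross-rank dispersion; classifies families into rigid, intermediate
    and flexible profiles; detects charge-transfer-center salt bridges in
    atomic structures at the 4.0 Angstrom cutoff; and correlates flexibility
    indices with gating charge, temperature coefficients (Q10) and
    stretch-induced activation shifts, including a modified single-exponential
    fit. A synthetic-data module generates alignments, toy structures and
    functional tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
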