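Package: gcxgcalign
Title: Anchor-Based Peak Alignment for Comprehensive Two-Dimensional Gas
    Chromatography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns peak tables from comprehensive two-dimensional gas
    chromatography with time-of-flight mass spectrometry (GCxGC-TOF).
    Implements six anchor-point detection algorithms (BiPACE 2D, DISCO,
    MSort, PAM, TNT-DA and a spectrum-aware Smith-Waterman), mass-spectral
    similarity scoring (Pearson or cosine, with an optional power
    transformation of intensities and m/z values), an elution-order
    consistency check, per-dimension retention-time shift correction,
    Kovats retention-index transformation, Kolmogorov-Smirnov and
    F1-score evaluation of alignment quality, and a synthetic
    chromatogram-pair generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
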