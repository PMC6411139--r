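Package: framescore
Title: Quality-Based Frame Scoring and Selection for Unstable Biomedical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns the relationship between per-frame image statistics and
    human 0-5 quality scores on a small scored sample of an image stack by
    stepwise multiple linear regression, predicts quality scores for every
    frame, and reduces the stack either by a quality cutoff or by a
    chronology-preserving frame-windowing scheme that keeps the best frame of
    each consecutive window. Includes two custom statistics designed for
    fluorescence intravital microscopy (sum pixel ramp, a stepped
    vertical-gradient sharpness proxy, and segment intensity deviation, a
    patchwise illumination-uniformity measure), coefficient persistence for
    scoring new stacks without fresh manual input, cross-set consolidation,
    agreement diagnostics against human scores, and a synthetic
    fluorescence-stack generator with known ground-truth quality for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
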