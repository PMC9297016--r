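Package: whoopsig
Title: Individual and Group Vocal Signatures in Long-Distance Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether long-distance animal vocalizations
    carry group-level and individual-level vocal signatures, built around
    the spotted hyena whoop. Provides a synthetic whoop-bout generator with
    known ground truth (clans, individuals, harmonic frequency-modulated
    calls in bouts), extraction of sixteen acoustic features per call
    (durations, fundamental-contour statistics, constant-frequency and
    upsweep segmentation, subharmonic energy ratios, normalized spectral
    entropy and cepstral peak prominence), leakage-proof random-forest
    cross-validation schemes for the clan- and individual-signature
    hypotheses with a composition-weighted chance expectation, permutation
    feature importance, and serial-redundancy accumulation curves over call
    bouts with exact and Monte-Carlo equal-informativeness baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
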