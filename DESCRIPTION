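Package: comfortEEG
Title: Single-Trial EEG Classification of Stereoscopic Visual Comfort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A passive brain-computer-interface pipeline that discriminates
    comfortable from uncomfortable stereoscopic viewing conditions from
    single-trial EEG. Provides a synthetic multichannel EEG cohort generator
    (1/f background, condition-dependent event-related potentials,
    alpha/theta band-power modulation, blink artifacts), band-pass filtering
    and epoching, automated artifact-epoch rejection, Fisher-criterion
    (regularized eigen Fisher) and common spatio-spectral pattern (CSSP)
    spatial filters, median-ratio feature selection, shrinkage linear
    discriminant classification, majority-vote trial aggregation with its
    binomial oracle, and cohort-level evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
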