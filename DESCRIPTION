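Package: kefbcsp
Title: Spectral-Spatial EEG Features via Filter-Bank Common Spatial
    Patterns and Kernel PCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts participant-independent features from multichannel
    resting-state EEG for two-class discrimination (e.g. patients versus
    controls). Implements the kernel eigen-filter-bank common spatial
    pattern (KEFB-CSP) pipeline: a bank of 3rd-order Butterworth band-pass
    filters over 4-44 Hz, common spatial pattern (CSP) transforms fitted
    per sub-band with normalized log-power features, and a Gaussian-kernel
    principal component analysis of the concatenated filter-bank CSP
    vector. Also provides the standard comparison features (band power,
    Welch magnitude-squared coherence, Grassberger-Procaccia correlation
    dimension), leave-one-participant-out cross-validation with k-NN, LDA
    and SVM classifiers, a majority-voting participant-level variant,
    grid search over the method parameters, EDF and delimited-text epoch
    I/O, and a synthetic EEG generator with known spatial ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    class,
    e1071,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
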