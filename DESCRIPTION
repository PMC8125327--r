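Package: emgstress
Title: Driver Stress Detection from Surface EMG with Statistical Time Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline for detecting driver stress from a single
    surface electromyography (EMG) channel sampled at low rate during a
    rest / city / highway driving protocol. Provides a seedable synthetic
    EMG cohort generator, fixed-window segmentation with rest-baseline
    z-score normalization, seventeen statistical time features (grouped
    mode, moments, RMS, square mean root, crest/impulse/latitude/shape
    factors), Kruskal-Wallis feature ranking, and cross-validated support
    vector machine and multilayer perceptron classifiers with a
    window-length by kernel study.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
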