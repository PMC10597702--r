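Package: ramanmtn
Title: Multi-Task Deep Learning for Raman Spectral Diagnosis of Oral Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for staging and grading oral lesions from fiber-optic Raman
    spectra with a single multi-task convolutional network. Provides spectral
    preprocessing (Savitzky-Golay smoothing, iterative polynomial baseline
    removal, min-max normalisation, class-balancing averaging, outlier
    screening), a class-conditional Lorentzian-peak spectrum simulator, a
    one-dimensional ResNet-50 backbone with three classification heads
    (T stage, N stage, histological grade) trained by stochastic gradient
    descent on a pure-BLAS engine, ten-fold cross-validated evaluation
    (sensitivity, specificity, macro ROC/AUC, cumulative confusion matrices),
    and Grad-CAM band-level interpretation of the fitted model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
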