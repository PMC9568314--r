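Package: ctartsim
Title: Simulation and Recognition of Artifacts in Head CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the three classic computed-tomography artifacts
    (patient-motion rotation, concentric detector rings, and beam hardening)
    on head-CT-like grayscale images, extracts compact singular-value
    spectra as image features, and trains binary support-vector-machine
    classifiers that recognise each artifact against the original images.
    Includes a seeded synthetic head-phantom generator emulating paranasal
    sinus / skull-base slices, Otsu histogram thresholding, repeated k-fold
    and leave-one-out cross-validation, ROC/AUC analysis, and
    confusion-matrix metrics (precision, recall, F-score), with tidy
    tibble outputs, broom-style tidy()/glance() methods and ggplot2
    autoplot() graphics throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
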