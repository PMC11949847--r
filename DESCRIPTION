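Package: gradecard
Title: Multimodal Quality Grading of Cardamom from Electronic-Nose and
    Image Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for grading cardamom capsules and seeds from
    two sensing modalities: six signal descriptors per metal-oxide gas
    sensor extracted from fractionally normalized electronic-nose
    recordings, and a 52-feature colour/texture battery (channel moments
    over RGB, HSV and CIELAB plus 16 gray-level co-occurrence texture
    descriptors) from product images. Includes correlation-based feature
    selection with best-first search, feature-level fusion of the two
    modalities, three classifier families (kernel SVM including the
    Pearson VII universal kernel, discrete Bayesian-network classifiers
    with K2 structure augmentation, gain-ratio decision trees with
    reduced-error pruning), a stratified split / cross-validation
    evaluation protocol, and a seeded synthetic-data generator that
    emulates the grade structure of the measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    kernlab,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
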