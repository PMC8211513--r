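Package: dxbayes
Title: Naive Bayes Diagnosis Ranking from Ordered Symptom Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate disease diagnoses from an ordered, free-text list
    of patient symptoms using a family of eight modified Naive Bayes
    classifiers built on per-symptom likelihood-ratio operators. Variants
    differ in their treatment of the class prior (empirical, omitted, or
    uniform "equal probability"), in scoring form (product or log), and in
    whether the first three "main" symptoms receive an extra weight
    coefficient. Includes corpus cleaning against a synonym lexicon,
    Laplace smoothing for disease-symptom pairs never seen together,
    stratified k-fold cross-validated top-k hit-accuracy evaluation, and a
    synthetic corpus generator with known Bernoulli emission structure for
    testing every variant without access to private medical-record data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
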