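Package: histotex
Title: Wavelet Texture and Colour-Moment Features for Grading Histological
    Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for grading
    H&E-stained prostate tissue patches. Computes one- and two-level Haar
    wavelet decompositions, gray-level co-occurrence matrix (Haralick)
    texture statistics over the wavelet sub-bands, and pixel-based colour
    moment descriptors; screens features by one-way MANOVA/ANOVA across
    grade groups; and classifies the five standard binary grade contrasts
    with a small multilayer perceptron trained by stochastic gradient
    descent with momentum. Includes a seeded synthetic H&E-like patch
    generator so the full pipeline is reproducible without clinical images,
    plus confusion-matrix utilities that recover integer counts from
    published accuracy/sensitivity/specificity triples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
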