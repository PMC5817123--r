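Package: cannorm
Title: Geometric Morphometrics of Cannibalism-Induced Dimorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing density- and
    interaction-driven cannibalistic dimorphism in larval salamander
    populations from landmark-based geometric morphometrics. Reads TPS
    landmark files and census/measurement tables, performs generalized
    Procrustes superimposition with bilateral symmetrization, quantifies
    morphological integration (Escoufier's RV coefficient and two-block
    partial least squares with permutation tests), fits and compares
    standardized major axis allometry lines, discriminates morph types by
    Procrustes-distance permutation tests and canonical variate analysis,
    summarises per-tank size/shape distributions (correlation and skewness
    reaction-norm statistics), and selects among competing exploitation and
    interference competition models by Akaike weights. Includes a synthetic
    dimorphic-population generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
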