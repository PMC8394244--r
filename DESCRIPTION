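Package: adeeg
Title: Quantitative EEG Biomarker Panels for Alzheimer's Disease Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end framework for deriving robust resting-state EEG
    biomarkers of Alzheimer's disease on the 10-20 montage. Computes eight
    signal-derived biomarker families (band power, amplitude change rate,
    zero-crossing intervals, Tsallis entropy, Higuchi fractal dimension,
    Lempel-Ziv complexity, approximate entropy, magnitude-squared coherence)
    per frequency band and band ratio; screens features and channels with
    two-sample tests, Bonferroni correction and cumulative probability
    distribution ratios; enumerates biomarker panels exhaustively; evaluates
    panels with cross-validated support vector machines; fuses surviving
    panels with linear discriminant analysis into a diagnostic model; and
    searches for minimal biomarker subsets. Includes a synthetic EEG cohort
    generator with controllable slowing, complexity-reduction and
    coherence-loss effects so every pipeline stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    e1071,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
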