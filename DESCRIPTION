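Package: scalpdose
Title: Scalp-Shell Dosimetry and Skin NTCP for Radiotherapy with Transducer Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying skin toxicity risk when scalp-mounted
    transducer arrays are worn during cranial radiotherapy. Builds 2 mm
    scalp shells from body masks by Euclidean distance transform, reduces
    3-D dose grids to cumulative dose-volume histograms and area hot-spot
    metrics (minimum dose in the hottest 0.05 and 25 cm2), computes the
    Luxton generalized equivalent uniform dose (gEUD), the Kutcher-Burman
    effective volume, and Lyman normal tissue complication probabilities
    (NTCP) for skin necrosis with the Burman skin parameterization.
    Includes a per-fraction dose accumulation and scenario engine for five
    electrode-positioning conditions, a synthetic head-phantom cohort
    generator with electrode placement variation, and the statistical layer
    (log-NTCP two-way ANOVA with multiplicative scenario factors, rank
    correlations, Lilliefors normality bands) used to assess how array
    position variation mitigates skin dose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    nortest,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
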