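Package: vertebrome
Title: MicroCT Phenomics of the Zebrafish Vertebral Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microCT-based skeletal phenomics in adult zebrafish.
    Reads calibrated microCT volumes (DICOM series), segments the vertebral
    column into per-vertebra neural arch, centrum and haemal arch/rib
    elements from user seed lines by separation-plane growing over connected
    components, and computes 25 morphological and densitometric measures per
    vertebra (volume, surface area, model-independent local thickness,
    tissue mineral density, and their intra-specimen variation, plus centrum
    length). Provides the accompanying statistical workflow: a global score
    test for differences in vertebral patterns between groups, skeletal
    barcodes (standard scores against a control population), pairwise
    correlation profiling, Royston multivariate-normality screening,
    allometric power-law normalization for body size, and a Monte-Carlo
    engine for sensitivity, specificity and power analysis of multivariate
    vertebral phenotypes. Synthetic spine phantoms with analytic ground
    truth make the full pipeline testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
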