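Package: mrdpi
Title: Prognostic Index Modelling and Risk Stratification for Pediatric B-ALL
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building, scoring, validating and discretizing Cox
    proportional-hazards prognostic indices for relapse risk in pediatric
    B-cell acute lymphoblastic leukemia. Implements the minimal-residual-
    disease log transformation with a detection floor, linear-predictor risk
    scoring with published coefficient sets, a multi-step external/internal
    validation battery (calibration slope, Harrell's concordance index,
    coefficient-equality testing, bootstrap optimism correction, calibration
    curves), Goenen-Heller concordance-probability-estimate cutpoint
    optimization into ordered risk groups, Kaplan-Meier risk-group comparison,
    a configurable clinical risk-classification rules engine, and a synthetic
    cohort generator emulating the covariate structure of the COG B-ALL
    trial population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
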