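Package: phenoconv
Title: CYP2D6 Phenoconversion, Drug-Exposure Eras, and IPTW Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacogenomic cohort studies of CYP2D6-metabolized
    opioids. Translates multi-caller star-allele reports into consensus
    diplotypes, activity scores and metabolizer phenotypes, applies
    inhibitor-mediated phenoconversion, stitches prescription records into
    drug-exposure eras with imputed end dates, assembles a new-user cohort
    with baseline covariates and a pain-related emergency-department visit
    outcome, and estimates unweighted and inverse-probability-of-treatment
    weighted odds ratios with robust confidence intervals and standardized
    mean difference balance diagnostics. Includes a calibrated synthetic
    electronic-health-record data generator with known counterfactual ground
    truth for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    sandwich,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
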