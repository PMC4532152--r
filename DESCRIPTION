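Package: copdcosts
Title: Top-Down Cost-of-Illness Accounting and Smoking-Standardised
    Cost Projection for COPD
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Register-based top-down accounting of the direct
    (hospitalisation, outpatient, medication) and indirect (sickness
    allowance, disability pension) costs of chronic obstructive pulmonary
    disease (COPD), together with a smoking-standardised projection model
    for future annual costs.  Includes a seeded synthetic register
    generator emulating the structure of national care, medication,
    allowance and pension registers, unit-cost inflation indexing,
    age-sex stratified smoking-prevalence extrapolation, and a
    reproducible end-to-end pipeline with delimited-text and JSON
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
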