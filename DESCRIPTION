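Package: dyadlds
Title: Latent Difference Score Models for Two-Informant Questionnaire Data
Version: 0.1.0
Authors@R:
    person("MCS", "Methods Group", email = "methods@example.org", role = c("aut", "cre"))
Description: Tools for quantifying informant discrepancy between parent and
    adolescent questionnaire reports. Implements a structural equation
    modelling engine with mean structure (maximum likelihood on weighted
    sample moments, full-information maximum likelihood for item-level
    missingness, sandwich standard errors), measurement-invariance testing
    across reporters with a capped partial-invariance search driven by
    modification indices, latent difference score (LDS) models with binary
    moderators, inverse-probability weighting for unit nonresponse, and a
    synthetic dyad generator with known latent truth for end-to-end
    validation. Scoring utilities for SDQ-style 3-point subscales and the
    Kessler-6 distress screen are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
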