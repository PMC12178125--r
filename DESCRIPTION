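Package: pfce
Title: Multi-Level Fuzzy Comprehensive Evaluation of Agronomic Treatment Schemes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-criteria evaluation of factorial field-trial
    treatments, developed around biochar application schemes (pyrolysis
    temperature by application rate) in potato cultivation. Implements derived
    agronomic indicators (water use efficiency, fertilizer partial factor
    productivity, net income, soil nutrient accumulation), subjective
    weighting by the analytic hierarchy process with consistency checking,
    objective entropy weighting, least-squares combination of the two weight
    vectors, five-grade fuzzy comprehensive evaluation with piecewise-linear
    membership functions, and quadratic response-surface optimization of the
    comprehensive score over the factor space. Includes a synthetic trial
    generator with known ground truth and transcribed example trial tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
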