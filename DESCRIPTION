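Package: easi
Title: Multi-Stage Simulation of Individual COPD Natural Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates individual natural histories of chronic obstructive
    pulmonary disease (COPD) with a four-stage feed-forward cascade linking
    smoking Exposure, inflammatory Activity, Severity of airflow limitation
    (FEV1) and perceived Impact (dyspnea). Stages are coupled by logistic
    threshold activation functions and first-order linear ordinary
    differential equations integrated with a fixed-step Euler scheme. Ships
    ten canonical parameterizations (six clinical scenarios and four patient
    profiles), decade heat-map and cross-scenario comparison tables, seeded
    Monte Carlo population ensembles with truncated-normal parameter
    dispersion, a random-search calibration loop against population lung
    function targets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
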