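Package: adesim
Title: Discrete Event Simulation for Cost-Effectiveness of Alzheimer's
    Disease Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level discrete event simulation of Alzheimer's disease
    progression on four correlated scales (MMSE, NPI, ADL, IADL), with
    treatment-persistence modelling, a Gompertz survival stand-in, German
    cost and utility inputs, and a cost-utility analysis layer (deterministic
    comparisons, one-way scenarios, and probabilistic sensitivity analysis
    with cost-effectiveness-plane summaries). Includes a Gaussian-copula
    synthetic cohort generator that emulates a donepezil-trial baseline
    population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
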