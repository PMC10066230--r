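Package: compostsem
Title: Multi-Stage Causal Inference for Compost-Amendment Multi-Omics Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the multi-stage inference pipeline
    used to link compost amendment to plant metabolites, soil metabolites and
    soil bacteria in two-arm field experiments: univariate screening with a
    normality-driven test-selection cascade, association-rule (lift) feature
    selection, from-scratch maximum-likelihood path-model (SEM) estimation
    with the seven-index fit battery (chi-square, CFI, TLI, RMSEA, SRMR, GFI,
    AGFI), exhaustive candidate-model enumeration and ranking, quasi-Bayesian
    causal mediation analysis (ACME/ADE), and Bayesian linear non-Gaussian
    acyclic model (BayesLiNGAM) comparison with mixture-of-Gaussian
    disturbances. A synthetic-data module generates field-experiment-like
    multi-omics datasets (metabolite panels, compositional taxa tables, taste
    contingency counts, root photographs) with known ground-truth causal
    structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
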