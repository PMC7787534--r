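Package: vhdepth
Title: Causal-Inference Modeling of Visuo-Haptic Depth Direction Judgments
Version: 0.1.0
Authors@R: person("vhdepth", "maintainers", email = "vhdepth@example.org",
    role = c("aut", "cre"))
Description: Fits and simulates two-alternative depth-direction judgments made
    while observers actively deform a visual surface with their hand. Provides
    maximum-likelihood cumulative-Gaussian psychometric fitting with PSE and
    JND extraction, a Bayesian causal-inference mixture model of visuo-haptic
    integration on a discretized depth axis (Gaussian haptic likelihood with a
    uniform no-common-cause tail; disparity-defined or shading-defined visual
    likelihoods with light-from-above and convexity priors), exhaustive
    grid-search parameter estimation with AIC model comparison, canonical
    folding of shading-trial light directions, synthetic-observer generation,
    and CSV/JSON input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
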