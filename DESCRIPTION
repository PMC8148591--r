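Package: stcmix
Title: Mixture Neurotoxicity Modelling for Zebrafish Embryo Tail Coiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Concentration-response analysis of zebrafish embryo spontaneous
    tail coiling (STC) and prediction of mixture neurotoxicity. Fits the
    four-parameter log-logistic model to percent-change STC data, standardizes
    hyperactivity curves to a common 100 percent maximum, predicts mixture
    effects under concentration addition (Loewe additivity) and independent
    action (Bliss independence), designs equitoxic and substitution mixtures,
    and evaluates antagonism of opposing-direction mixtures with a biphasic
    Gaussian model. Includes a seeded generator of embryo-level STC count
    datasets mirroring the 20-embryo, two-replicate, multi-experiment assay
    design, so the whole pipeline is testable without raw laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
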