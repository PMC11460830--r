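Package: ehrbias
Title: Information-Bias Analysis for EHR-Based Disease Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and correcting outcome misclassification in
    electronic health record (EHR) research. Provides a synthetic EHR
    generator whose causal structure encodes informed-presence and
    diagnostic-suspicion bias (true chronic-disease states, overdispersed
    utilization that is a common effect of disease, per-encounter
    documentation so that false negatives dominate and specificity is
    near-perfect), rule-based computable phenotypes for diabetes, asthma and
    obesity, four odds-ratio estimation strategies (naive, data-sufficiency
    restriction, stabilized inverse-probability weighting, and adjustment
    for health-care utilization), a design-based survey benchmark with
    Taylor-linearized variance, and a replicated simulation harness
    reporting bias, coverage and percent differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
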