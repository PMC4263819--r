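Package: blindinsight
Title: Signal-Detection Analysis of Metacognition Without First-Order Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-level analysis of artificial-grammar-learning
    (AGL) experiments with confidence ratings. Computes Type I and Type II
    signal-detection indices (d-prime, decision criterion, Type II d-prime,
    confidence-accuracy slope) and maximum-likelihood meta-d-prime; implements
    a regression-to-the-mean-robust participant selection that classifies
    performers on early test trials and analyzes their later trials; provides
    an inferential battery (contrast-based within-subject ANOVA, linear trend
    test, pooled t tests, half-normal Bayes factor); and runs parametric
    Monte Carlo signal-detection simulations (unequal-variance null and
    criterion-jitter) that probe artifactual explanations of
    confidence-accuracy dissociations. A synthetic-data generator produces
    AGL-like cohorts under either a hierarchical signal-detection observer or
    an independent error-monitoring channel, so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
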