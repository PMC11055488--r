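Package: effortbench
Title: Simulation and Analysis of Behavioral Listening-Effort Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze dual-task behavioral listening-effort
    experiments in cochlear-implant users. Provides a synthetic-data generator for
    sentence verification (true/false categorization with reaction times) and
    sentence-final word identification and recall tasks driven by per-listener
    psychometric functions; a stochastic-approximation adaptive procedure for
    estimating the 50% speech reception threshold (SRT50); preprocessing steps
    (response-validity filtering, reaction-time shifting, exact-tail item outlier
    detection, learning-effect correction); generalized linear mixed models with
    crossed random effects (Gamma log-link for reaction times, binomial logit for
    accuracy, repetition and recall) including AIC backward selection,
    likelihood-ratio tests for interactions, standardized coefficients, Nakagawa
    R-squared and overdispersion checks; and intra-individual detection thresholds
    derived from test-retest variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
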