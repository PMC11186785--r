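Package: stocclock
Title: Stochastic Simulation and Evaluation of Epigenetic Clocks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how much of an epigenetic clock's accuracy
    could be explained by purely stochastic DNA-methylation change. Provides
    a two-state Markov model of single-cell CpG methylation dynamics, a
    population-level simulator that accrues signed half-normal deviates in
    inverse-normal-quantile space, recursive grid-search estimation of the
    simulator's two parameters (global alteration rate gamma and deviate
    scale sigma) from young/old reference panels, elastic-net training of
    "stochastic clock" analogues on simulated cohorts, RR2 (ratio of
    R-squared) quantification of a clock's stochastic component, and
    extrinsic/intrinsic epigenetic age-acceleration (EAA/IAA) analysis with
    immune-cell-fraction adjustment. A synthetic-data module emulates
    young/old sorted-cell reference panels and whole-blood aging cohorts so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
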