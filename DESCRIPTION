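Package: lifetab
Title: Age-Stage Two-Sex Life Tables with Bootstrap Inference for
    Host-Plant Resistance Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for age-stage, two-sex life table analysis of insect
    cohorts reared on different diets or host plants.  Computes age-stage
    survivorship and fecundity matrices, the age-specific survival (lx)
    and fecundity (mx) schedules, and the demographic parameters GRR, R0,
    the intrinsic rate of increase r (Euler-Lotka), the finite rate lambda
    and the mean generation time T.  Provides individual-level bootstrap
    standard errors and percentile confidence intervals, paired-bootstrap
    treatment comparisons with compact letter displays, one-way ANOVA and
    Tukey HSD for enzyme-activity replicate tables, Ward minimum-variance
    clustering of treatments with Newick export, an individual-based
    synthetic cohort simulator with analytic expectations for validation,
    and a config-driven end-to-end pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
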