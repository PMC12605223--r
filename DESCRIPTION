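Package: osimcea
Title: Cost-Effectiveness of Osimertinib Consolidation in Unresectable
    Stage III EGFR-Mutated NSCLC
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-state (progression-free, progressed, dead) cohort
    cost-utility model comparing osimertinib consolidation with placebo
    after chemoradiotherapy in unresectable stage III EGFR-mutated
    non-small cell lung cancer, from the payer perspectives of the United
    States and China. Provides Weibull survival extrapolation with
    AIC/BIC-based selection among five parametric families, a partitioned
    survival cohort engine with discounting and half-cycle correction,
    incremental cost-effectiveness (ICER) and net health benefit (INHB)
    accounting, one-way (tornado) and probabilistic sensitivity analyses
    with cost-effectiveness acceptability curves, hazard-ratio-driven
    subgroup analyses, and a synthetic pseudo individual-patient-data
    generator emulating reconstruction of digitized Kaplan-Meier curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse
Config/testthat/edition: 3
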