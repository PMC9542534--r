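Package: qmpinfant
Title: Quantitative Microbiota Profiling and Birth-Exposure Analysis for
    Infant Gut Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for qPCR-anchored quantitative microbiota profiling (QMP)
    of longitudinal infant-gut 16S rRNA amplicon data: blank-control
    contaminant subtraction, rare-read and coverage filtering, 16S copy-number
    corrected absolute abundance estimation, birth-mode by intrapartum
    antibiotic exposure-group construction, covariate-adjusted taxon-wise
    differential abundance via a negative binomial / Poisson / quasi-Poisson /
    generalized-least-squares model cascade with Benjamini-Hochberg control,
    principal coordinates analysis on Pearson-correlation distances with
    per-timepoint group tests and smoothed class trajectories, and AIC-selected
    mediation path models linking birth exposures, absolute taxon abundances
    and infant gastrointestinal symptoms. Includes a longitudinal cohort
    simulator with planted ground truth for validation and power analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    sandwich,
    vegan,
    yaml,
    biomformat,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
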