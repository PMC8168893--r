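Package: csfcoupling
Title: Coupling Between the Global fMRI Signal and CSF Inflow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the coupling between the resting-state global
    blood-oxygen-level-dependent (BOLD) signal and the cerebrospinal fluid
    (CSF) inflow signal measured at the bottom slice of an fMRI acquisition.
    Provides temporal preprocessing (zero-phase band-pass, polynomial
    detrending, edge-volume discard) and mask-based signal extraction from
    4D NIfTI-1 series, lagged cross-correlation functions with a
    session-shuffling permutation null, session-level arousal and head-motion
    metrics, and a covariate-adjusted association battery built on linear
    mixed models with subject random intercepts and Satterthwaite degrees of
    freedom. A synthetic-cohort generator with a known coupling gain and
    delay makes every stage testable without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
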