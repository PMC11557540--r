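Package: prostasim
Title: Patient-Specific Finite-Element Simulation of Prostate Tumour Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation of localized prostate cancer growth under
    active surveillance, driven by patient-specific MRI biomarkers. Apparent
    diffusion coefficient (ADC) maps are converted to tissue cellularity and,
    together with biopsy tumour burden, into tumour-cell, healthy-cell and
    stroma densities on a tetrahedral finite-element mesh of the prostate;
    DCE-MRI KTrans maps drive oxygen delivery and PSA exchange with blood.
    Constituent dynamics (logistic proliferation and hypoxic death gated by
    oxygen thresholds), per-element oxygen equilibria with Michaelis-Menten
    consumption, serum/tissue PSA kinetics, and morphoelastic volumetric
    growth (multiplicative decomposition realized through a thermal-expansion
    eigenstrain analogy with rule-of-mixtures stiffness and elastic-foundation
    boundary springs) are integrated in a multiscale time loop. A two-stage
    multi-objective calibration (tree-structured Parzen estimator) fits growth
    and PSA parameters to follow-up observables. A synthetic-patient generator
    provides complete, reproducible test cases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    deSolve,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
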