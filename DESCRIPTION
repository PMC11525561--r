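Package: lcatpam
Title: Conformational-Metric Screening and Kinetic Workup for LCAT Activators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking a molecular-dynamics-derived
    conformational statistic (the CYS50-ASN65 alpha-carbon distance of the
    membrane-binding domain of lecithin-cholesterol acyltransferase) to
    enzymatic activation by small-molecule positive allosteric modulators.
    Provides multi-model PDB trajectory readers, distance time-series
    summarization (block averaging and replicate means with SEM), linear
    calibration of activity against the conformational metric with
    prediction intervals, virtual-screen triage filters (formal charge,
    molecular-mass window, docking-score cut-off), plate-assay kinetics
    (standard curves, Michaelis-Menten, catalytic efficiency, four-parameter
    logistic EC50), one-way ANOVA with Dunnett many-to-one comparisons, and
    seeded synthetic-data generators for every input so the whole pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
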