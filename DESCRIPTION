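Package: bnctcp
Title: Tumor Control Probability Modelling for Boron Neutron Capture Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Radiobiological dose-response toolkit for single high-dose
    boron neutron capture therapy (BNCT) of head and neck squamous cell
    carcinoma. Implements four clonogenic cell-survival models (linear
    quadratic, universal survival curve, linear quadratic linear, and Pade
    linear quadratic) with constrained nonlinear least-squares fitting and
    standard-error-of-estimate model comparison; biologically effective
    dose (BED) and 2-Gy-fraction equivalent dose (EQD2) isoeffect
    conversion of RBE/CBE-weighted BNCT doses under the universal survival
    curve; dose-volume histogram (DVH) input/output and dose metrics;
    generalized equivalent uniform dose (gEUD) reduction; and a logistic
    EUD-based tumor control probability (TCP) model with response
    classification. Seeded synthetic generators for survival datasets and
    parametric DVH cohorts make every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
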