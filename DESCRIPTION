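Package: tibiofit
Title: Population Finite-Element Study of Cementless Tibial Tray Primary Fixation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for population-based finite-element analysis
    of the primary fixation of cementless tibial knee components. Generates
    reproducible synthetic patient cohorts with tibia-like geometry and
    Hounsfield-unit bone density fields, performs automated implant
    reconstruction (anatomical frame assignment, rigid coherent point drift
    registration, tray sizing under an overhang bound, bone cuts,
    tetrahedralization), calibrates elastic-plastic bone material from CT
    intensities, solves quasi-static nonlinear frictional press-fit contact
    with linear tetrahedra and Von Mises plasticity under multi-cycle gait
    and squat loading, extracts implant-bone interface micromotion fields
    (peak, 95th percentile, osseointegration-threshold maps), and fits
    linear mixed-effects models of micromotion on patient factors
    (gender, age, BMI) with a random intercept per patient.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    stats,
    utils,
    jsonlite,
    yaml,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
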