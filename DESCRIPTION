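Package: pfasim
Title: Electric Field, Thermal Damage and Electrogram Modelling for Cardiac Pulsed Field Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling focal pulsed field ablation (PFA) of the
    ventricles. Builds an idealized biventricular geometry with inferior vena
    cava and catheters on a graded hexahedral grid, assigns rule-based
    myocardial fiber frames from a Laplace transmural coordinate, and solves
    the stationary nonlinear anisotropic conduction problem with
    field-dependent myocardial conductivity and scar blending. Lesion volumes
    are inverted into lethal electric field thresholds (LET) by bisection and
    summarised by dose with a power-law fit. A transient pulsed Joule-heating
    solver with analytic laminar blood-flow cooling yields thermal-dose and
    Arrhenius damage volumes. Intracardiac electrogram records are analysed
    for per-beat bipolar amplitude and unipolar current of injury, and
    biplane fluoroscopic catheter traces are reconstructed in 3-D. Seeded
    synthetic-data generators provide every pipeline input with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
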