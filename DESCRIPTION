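Package: hipshapes
Title: Statistical Shape Modeling of Hip Morphology with Cluster-Robust
    Outcome Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based statistical shape modeling of the hip joint on
    anteroposterior radiograph contours: Generalized Procrustes alignment of
    82-point configurations, principal-component shape modes with a
    variance-explained inclusion rule, dichotomization of SHOMRI cartilage
    and labral grades into binary early-osteoarthritis outcomes, and
    per-mode logistic association via generalized estimating equations with
    sandwich (cluster-robust) variance for the two hips of each participant.
    Includes a synthetic cohort generator with known deformation modes and
    effect sizes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
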