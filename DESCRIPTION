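Package: morphosex
Title: Sex Classification of 3D Sacrum Landmark Data by Geometric
    Morphometrics, Osteometric Indices and Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying skeletal sexual dimorphism from 3D
    landmark configurations of the human sacrum and for assessing sex
    classification accuracy.  Implements generalized Procrustes analysis
    with thin-plate-spline bending-energy semilandmark sliding, principal
    component analysis in shape and form space, multivariate
    variance-explained regressions, allometry-corrected sex effects,
    permutation tests on Procrustes distances, Procrustes ANOVA with
    residual randomization, osteometric indices (corporo-basal and
    corpus-area indices), two-group linear discriminant analysis with
    leave-one-out cross-validation, prevalence-weighted accuracy, ROC/AUC,
    Box's M, and observer-agreement statistics.  A synthetic
    landmark-population generator with exported ground truth makes the
    whole pipeline exercisable and testable without access to skeletal
    specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
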