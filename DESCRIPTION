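Package: scotoperim
Title: Analysis of Dark-Adapted Two-Color (Scotopic) Microperimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dark-adapted two-color (cyan/red)
    fundus-controlled perimetry ("scotopic microperimetry") exams as used in
    outcome-measure studies of rod-cone degenerations such as choroideremia.
    Provides test-grid geometry, exam file input/output, reliability gating
    (fixation losses, bivariate contour ellipse area, Fujii fixation
    classification, rod-free zone detection), pointwise/mean/volumetric
    sensitivity indices including hill-of-vision integration over a Delaunay
    triangulation, cyan-red difference maps and classifications,
    repeated-measures Bland-Altman repeatability with mixed-effects
    within-subject standard deviations and cluster bootstrap confidence
    intervals, cohort summary statistics, structure-function correlation, and
    a synthetic-cohort generator with a 4-2 staircase psychophysical observer
    for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
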