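Package: podoscope
Title: Design-Based Podometrics and Glomerulosclerosis Scoring for Kidney Biopsies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators and cohort statistics for quantitative podocyte
    morphometry (podometrics) in diagnostic kidney biopsies. Implements
    design-based stereological estimators of podocyte number, density and
    nuclear, cytoplasmic and total volumes from thin confocal optical
    sections (Weibel-Gomez glomerular volume, caliper-diameter corrections,
    confocal axial-resolution section thickness), semiquantitative
    glomerulosclerosis scoring (glomerulosclerotic index, percent global
    sclerosis, percent segmental lesions) with threshold classifiers, an
    automated image-measurement stage (IsoData thresholding, podocyte
    nucleus detection with parietal-cell exclusion, XY caliper diameters),
    CKD-EPI eGFR and remission classification, a normality-gated two-group
    statistical layer with exact Mann-Whitney and 2x2 chi-square tests, and
    a fully seeded synthetic glomerulus and cohort generator that provides
    ground truth for every stage.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
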