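Package: coneagree
Title: Agreement Analysis for Cone Photoreceptor Mosaic Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the repeatability and reliability of cone
    photoreceptor identifications in adaptive-optics retinal images. Provides
    adaptive nearest-neighbour distance thresholds for point-set matching,
    one-to-one pairwise correspondence and multi-grader clustering of cone
    selections, true/false positive rates and Dice's coefficient, Voronoi
    tessellation with bound cone density, Bland-Altman analysis with automatic
    log10 transformation, intraclass correlation with confidence intervals,
    repeated-measures ANOVA with Bonferroni-corrected post hoc tests, and a
    synthetic cone-mosaic and annotation-noise generator for closed-loop
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    deldir,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
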