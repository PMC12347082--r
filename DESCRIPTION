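Package: gnathodiff
Title: Quantifying Differences Between Orthognathic Surgical Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional difference between
    two orthognathic surgical plans for the same patient, such as a
    pretreatment plan (T0) and a presurgical plan (T1). Osteotomized
    segments are registered by landmark-initialized trimmed iterative
    closest point matching; anatomical landmarks on the dental maxilla,
    dental mandible, and bony mandibular distal segment span virtual
    triangles whose rigid (Kabsch/Procrustes) transforms are decomposed
    into six clinical degrees of freedom per segment (pitch, roll, yaw in
    degrees; left-right, antero-posterior, and vertical translation in
    millimetres). A cohort statistics layer reproduces the standard
    reporting: one-sample t-tests with SEM and 95% confidence intervals,
    top-10% absolute values, out-of-range percentages against clinical
    tolerances (2 mm, 4 degrees), and unpaired subgroup contrasts. A
    synthetic-cohort generator with known ground truth supports
    end-to-end parameter-recovery validation.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
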