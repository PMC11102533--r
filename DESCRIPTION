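Package: hpagrade
Title: Automated Hodapp-Parrish-Anderson Grading of Glaucomatous Visual Field Defects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades Humphrey-style perimetry results on the Hodapp-Parrish-Anderson
    (HPA) severity scale (none, mild, moderate, severe) from three inputs: mean
    deviation, the four central global-plot sensitivities, and the pattern-deviation
    probability plot. The pattern-deviation plot may be supplied as numbers or as a
    raster image (PNG, JPEG, TIFF); an interpretable computer-vision parser locates
    the plot panel, superimposes the canonical 24-2 or 30-2 test-locus grid, and
    classifies the probability symbol at each locus by ink density. Includes a
    synthetic Humphrey-style plot renderer with known ground truth for validation,
    and the agreement statistics (Cohen's kappa, sensitivity, specificity, accuracy,
    F1 with explicit undefined-value semantics, Welch's t from summary statistics)
    used to certify the grader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    withr,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jpeg,
    e1071,
    readr,
    optparse
Config/testthat/edition: 3
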