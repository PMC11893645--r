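Package: spinegrowth
Title: Longitudinal Spine Growth Analysis and Adult Spine Height Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs T1-S1 spine height from longitudinal anthropometric
    and radiographic landmark measurements by three complementary methods,
    aligns children on adolescent growth-spurt timing (the age at 90% of
    adult standing height, PGA90), derives growth-remaining multiplier
    tables and phase-wise spinal growth velocities, and predicts adult
    spine height with method-based bounds. Includes a synthetic longitudinal
    cohort generator calibrated to published multiplier and velocity tables
    so the whole pipeline is testable end to end, plus an external
    consistency check against pelvic-width spine-length predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
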