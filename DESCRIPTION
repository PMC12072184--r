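Package: greyhormone
Title: Grey Relational Analysis of Phytohormone Ratios and Plant Height
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking phytohormone-ratio features against a plant
    growth trait with Deng's grey relational analysis (mean-value
    normalization, grey relational coefficients with a resolution
    coefficient, grey relational degrees, ranks), together with Pearson
    height-ratio correlation with significance stars, a fold-change plus
    t-test differential-protein screen, a seeded synthetic-data generator
    calibrated to soybean blue-light hormone profiles, and an end-to-end
    pipeline with CSV and JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
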