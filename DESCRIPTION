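Package: relsev
Title: Relative Severity Assessment for Animal Welfare Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multi-variable animal-welfare time courses (body weight,
    burrowing, heart rate, heart rate variability, temperature, activity) into
    a single reference-anchored relative severity (RELSA) score per animal and
    time point. Builds reference sets of maximal baseline deviations, computes
    per-variable severity weights and their root-mean-square composite,
    extracts per-animal score maxima, derives data-driven severity levels by
    univariate k-means clustering (with an exact dynamic-programming mode),
    and quantifies uncertainty with bias-corrected and accelerated (BCa)
    bootstrap confidence intervals. Includes a synthetic cohort generator for
    validation and a command-line interface for the full pipeline.
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
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
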