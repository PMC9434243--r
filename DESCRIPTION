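Package: rhoadx
Title: Semi-Automated Radiographic Hip Osteoarthritis Grading from DXA Hip Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading radiographic hip osteoarthritis (rHOA) from
    annotated dual-energy X-ray absorptiometry (DXA) hip images. Computes
    superior minimum joint space width from an 85-point left-hip outline,
    quantifies osteophyte area from marked-up polygons at three joint-margin
    sites, applies threshold-based semi-quantitative grades and a composite
    rHOA grade (0-4), and runs the downstream clinical-association pipeline
    (prevalence tabulation, logistic and Cox proportional-hazards models with
    covariate adjustment, sex interactions and stratification). Includes a
    calibrated synthetic generator for hip geometry and cohorts so the full
    pipeline can be exercised and validated without access-controlled data.
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
    survival,
    tibble,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
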