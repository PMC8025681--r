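Package: funnelprof
Title: Risk-Adjusted Funnel Plots for Surgeon Outcome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling individual surgeons on binary surgical
    outcomes, built around arthroplasty-register practice: funnel plots of
    per-surgeon event proportions against annual volume with control limits
    from Wilson score intervals (upper 95% and 99.8%), logistic risk
    adjustment for patient case mix, and indirectly standardized proportions
    (observed/expected times the overall rate). Includes a calibrated
    synthetic registry generator emulating a regional hip-arthroplasty
    cohort, inclusion filters (complete-case, simultaneous-bilateral
    collapse, annual volume thresholds), and report rendering for annual
    outlier-count tables and funnel figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
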