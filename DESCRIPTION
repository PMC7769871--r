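Package: pigamu
Title: Antimicrobial Usage Quantification for Farrow-to-Finish Pig Farms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies veterinary antimicrobial usage on farrow-to-finish pig
    farms with the Swiss defined daily dose (DDDch) metric. Converts
    prescription records into numbers of defined daily doses (nDDDch) and
    nDDDch per animal and year, stratified by age category (piglets, weaners,
    fatteners, sows) and antimicrobial class, including the share of highest
    priority critically important antimicrobials (HPCIA). Provides the
    descriptive and inferential layer used in usage monitoring (category and
    class distribution tables, Kruskal-Wallis with Bonferroni-corrected
    post-hoc comparisons, within-herd and herd-size regressions) and a
    calibrated synthetic cohort generator so the full pipeline is testable
    without confidential farm records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
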