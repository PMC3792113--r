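Package: oncoscreen
Title: Cancer Versus Normal Expression Screening with Rank-Based Gating
    and Median-Rank Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-implements the Oncomine-style differential-expression screen
    used to survey gene families across cancer microarray studies. For each
    study it computes per-gene pooled-variance Student's t statistics on log2
    intensities, signed linear fold changes, p-value gene ranks and rank
    percentiles, and rank-based false-discovery Q-values (Q = NP/R). A
    three-criterion Boolean-AND gate (p < 0.05, |fold change| >= 2, rank
    percentile <= 10) extracts above-threshold analyses, which are summarised
    by cross-study median p-value and median gene rank meta-analysis (n >= 5
    datasets), mean +/- SEM fold aggregation, and over/under gene-by-cancer
    summary matrices. A seed-deterministic multi-study simulator with planted
    over- and under-expressed genes makes the whole pipeline testable without
    access to the defunct Oncomine database.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
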