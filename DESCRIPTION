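Package: wcstsplit
Title: Split-Half Reliability Analysis for the Computerized Wisconsin Card
    Sorting Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing trial-level data from a computerized
    Wisconsin Card Sorting Test (cWCST). Classifies trials as switch, repeat
    and inference trials, scores perseveration, set-loss and inference
    errors, applies participant-level validity screening and trial-level
    response-time exclusions, and estimates split-half reliability of error
    and response-time measures under systematic (first/second, odd/even)
    and sampled random test splits with Spearman-Brown correction and 95%
    highest-density-interval summaries. Includes a generative agent model of
    cWCST performance for cohort simulation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
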