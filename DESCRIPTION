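Package: copentropy
Title: Sample Entropy Analysis of Center-of-Pressure Postural Sway
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end regularity analysis of force-plate postural sway
    recordings: center-of-pressure (COP) computation from ground reaction
    forces and moments, zero-phase Butterworth low-pass filtering, COP
    displacement increment series, sample entropy (SampEn) with a
    brute-force verification oracle, and cohort-level statistics
    (two-way mixed-design ANOVA with generalized eta squared, assumption
    checks, Bonferroni-corrected pairwise post hocs). Includes a
    synthetic sway and cohort generator with controlled regularity
    (MIX-type processes) so every pipeline stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
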