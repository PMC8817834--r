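Package: mrlong
Title: Two-Sample Mendelian Randomization for Circulating Antioxidants and Longevity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization toolkit built around
    the question of whether long-term circulating antioxidant exposure affects
    human longevity. Reads and validates GWAS summary statistics, harmonizes
    exposure and outcome effects onto a shared effect allele, and estimates
    causal effects with the inverse-variance weighted method under a
    multiplicative random-effects model, the weighted median, MR-Egger
    regression, and the MR-PRESSO outlier framework, alongside Cochran's Q,
    leave-one-out, instrument-strength (F statistic) and statistical-power
    diagnostics. A seeded synthetic summary-statistics generator with known
    causal effects and configurable pleiotropy regimes makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
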