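Package: scatniche
Title: Dietary Niche Breadth and Trophic Level Analysis from Predator Scats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the dietary niche of a semi-aquatic predator from
    scat contents and fecal stable isotopes. Tabulates prey occurrences from
    long-format scat records, computes Levin's niche breadth (raw and
    standardized) with scat-resampling bootstrap confidence intervals,
    analytic Mao Tau species-accumulation curves, and fractional trophic
    level from diet composition and a prey trophic-level lookup. Isotope
    tools cover delta notation, variance-based isotopic niche width with
    Levene's homoscedasticity test, two-factor ANOVA and Bonferroni pairwise
    contrasts, plus trophic-enrichment-factor conversion of delta-15N shifts
    to trophic-level shifts. A synthetic scat and isotope generator with
    known diet composition supports end-to-end testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
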