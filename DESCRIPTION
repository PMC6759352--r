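Package: wolftooth
Title: Tooth Fracture, Wear and Carcass Utilization Analysis for Gray Wolf Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-sectional analysis of dental fracture and wear in gray wolf
    (Canis lupus) skull samples, and of skeletal-element survival at kill sites,
    as used to relate carnivore tooth damage to prey availability. Provides
    validated readers and writers for per-tooth skull records and kill-site
    necropsy tables, per-individual and per-tooth fracture frequencies with and
    without canines, tooth-class and age-class stratification, wear-stage
    distributions, chi-square and two-proportion comparisons between samples,
    a skeletal utilization index with yearly series and moving-average
    smoothing, and a synthetic-data subsystem: deterministic fixtures that
    invert printed marginal percentages into exact integer datasets, and an
    age-structured annual-hazard simulator with maximum-likelihood hazard
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
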