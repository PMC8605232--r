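Package: aviarytransect
Title: Transect-Based Welfare Assessment for Loose-Housed Laying Hens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for whole-flock welfare surveillance of laying hens in
    multitiered aviary systems. Models house geometry and apportions the flock
    to walking transects under a homogeneous-distribution assumption, encodes
    three indicator scoring schemes (a 12-indicator binary whole-flock transect
    scheme and two 50-bird graded schemes), estimates indicator prevalences
    with standard errors, compares flocks, observers and house locations with
    binomial logit models (likelihood-ratio tests and Tukey-adjusted pairwise
    contrasts of least-squares means), computes tie-aware Spearman correlations
    between assessment methods, and provides a seeded flock simulator for
    sampling-design power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    emmeans,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
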