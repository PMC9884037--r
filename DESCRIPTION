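Package: camoccu
Title: Camera-Trap Community Metrics and Single-Season Occupancy Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for single-season camera-trap
    surveys of terrestrial mammal communities. Collapses raw photographic
    records into independent detection events (configurable independence
    interval, 60 minutes by default) and computes relative abundance indices
    (events per 100 trap-days). Summarises community structure through
    sample-based rarefaction, first-order Jackknife richness, Shannon-Wiener
    and Gini-Simpson diversity, and Jaccard/Sorensen between-community
    similarity. Builds daily detection/non-detection histories, collapses
    them into multi-day sampling occasions, and fits zero-inflated
    detection (site-occupancy) models with logit-linear covariates on
    occupancy and detection by maximum likelihood. Model adequacy is
    assessed with a parametric-bootstrap goodness-of-fit test and an
    overdispersion statistic (c-hat), which also drives the choice of
    occasion length. Candidate covariate structures are ranked by QAICc in
    a two-stage (detection first, then occupancy) selection, with
    variance-inflation-factor screening and confidence-interval based
    strength-of-evidence classification. A synthetic-survey generator with
    known parameters supports testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
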