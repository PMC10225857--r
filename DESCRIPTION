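Package: avitrend
Title: Trends in Total Abundance and Biomass of Breeding-Bird Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating change in the total
    abundance and biomass of breeding-bird assemblages from multispecies
    monitoring data. Raw annual index series are filtered with standard
    inclusion rules (zero-offset handling, coverage and span thresholds),
    smoothed with penalized-spline generalized additive models, and combined
    with absolute population estimates in a Bayesian hierarchical model that
    shrinks uncertain species trends towards habitat-by-migration group means
    and propagates uncertainty in both index values and population estimates.
    Downstream tools compute biomass trajectories via body-mass weighting,
    climate suitability trends (logit-slope regression on modelled annual
    suitability), abundance quartile classes, trait-correlate models
    (ordinary and phylogenetic least squares with Pagel's lambda, with
    all-subsets AIC selection), two-segment breakpoint regression on log
    totals, and change decompositions that respect draw-level accounting
    identities. A synthetic-assemblage simulator with known ground truth
    supports calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
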