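Package: dualtraj
Title: Longitudinal Metabolomic Signatures of Dual Memory and Gait Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline linking concurrent decline in
    verbal memory and usual gait speed in older adults to longitudinal plasma
    metabolomic signatures. Provides per-subject annual-slope estimation and
    tertile-based phenotype classification (no decline, memory decline only,
    gait decline only, dual decline), limit-of-detection filtering and
    left-censored imputation of quantified metabolite panels, per-metabolite
    linear mixed-effects screening with joint and pairwise group-by-time
    contrasts and Benjamini-Hochberg false-discovery-rate control, a panel of
    nine physiological metabolite ratios (Fischer ratio, GABR, IDO activity
    and others), competitive metabolite-class enrichment, and weighted
    correlation-network module detection with hub metabolites and
    eigen-metabolite scores. A seed-deterministic synthetic-cohort generator
    with planted ground truth makes every stage exercisable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
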