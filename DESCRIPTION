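Package: lifetraj
Title: Life-Calendar Employment Trajectories, Sequence Typologies, and
    Outcome Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for life-course epidemiology with retrospective
    life-calendar data. Represents yearly categorical employment state
    sequences aligned over a common age span, computes timing-sensitive
    Hamming dissimilarities, clusters sequences with a deterministic
    partitioning-around-medoids (PAM) algorithm, selects the number of
    trajectory types by average silhouette width, summarises typologies
    with chronograms and composition tables, and estimates
    covariate-adjusted odds ratios relating trajectory membership to a
    binary health outcome. Includes a synthetic-cohort generator that
    emulates gendered panels of employment sequences, baseline
    covariates, attrition, and logistically generated outcomes, so the
    whole pipeline can be exercised without access-restricted survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
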