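Package: tailnet
Title: Association and Tail-Biting Interaction Networks in Group-Housed Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds half-weight-index (HWI) association networks from
    scan-sampled lying observations and directed, bite-count-weighted
    interaction networks from tail-biting event logs in growing-finishing
    pig pens.  Provides a self-contained graph-metric engine (density,
    strength, Brandes betweenness, Freeman centralization) for small
    weighted networks, tail-injury scoring (maximal tail score,
    victimization), and the statistical layer used to relate network
    position to injury: Kruskal-Wallis rank tests with post hoc
    comparisons, linear mixed models with Tukey-adjusted estimated
    marginal means, proportional-odds models for ordinal injury scores,
    and mixed-effects logistic models for victimization.  A synthetic
    pen-behavior generator reproduces the statistical structure of the
    study design (litter-origin treatments, scan-sampled lying bouts,
    Poisson bite streams, injury trajectories) so the full pipeline is
    testable without access to raw video-derived data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    nnet,
    lme4,
    emmeans,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
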