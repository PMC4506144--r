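Package: galton
Title: Robustness Tests for Cross-Cultural Correlations Under Phylogenetic
    and Geographic Non-Independence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a correlation between a group-level
    cultural trait (such as strong versus weak grammatical future-time
    reference) and an individual-level binary outcome (such as reporting
    having saved money) survives corrections for the shared descent and
    geographic proximity of the sampled languages (Galton's problem).
    Implements classification-based phylogeny construction with explicit
    branch-depth assumptions, crossed random-effects logistic models,
    regression on matched samples with per-language residualisation,
    simple, partial and stratified Mantel permutation tests, Moran's I and
    geographically weighted regression, Pagel's lambda and the
    Fritz-Purvis D signal statistics, phylogenetic generalised least
    squares with influence diagnostics and branch-length sweeps,
    independent-family Monte-Carlo sampling, and a synthetic-data
    generator that reproduces the statistical structure every stage
    assumes, so the whole battery is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    survival,
    sandwich,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    phangorn,
    vegan,
    nlme,
    withr
Config/testthat/edition: 3
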