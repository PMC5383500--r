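Package: funneigh
Title: Functional Neighborhoods, Dark Diversity, and Species Establishment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trait-based modelling of community assembly filters for
    predicting species establishment. Splits a regional species list into
    environmentally excluded species, dark diversity, and the observed
    community; models environmental filtering (regional list versus
    habitat-specific species pool) and biotic filtering (observed community
    versus dark diversity) as binomial regressions on Gower trait
    dissimilarities measured over tunable functional neighborhoods; selects
    neighborhood size and trait interactions by AICc with degeneracy
    diagnostics; and combines filter-passage probabilities into establishment
    predictions validated against seed-addition outcomes. Includes a
    community-assembly simulator (environmental filtering, weak phenotype
    exclusion, limiting similarity) with known truth for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'pools.R'
    'traitTable.R'
    'distances.R'
    'funneigh-package.R'
    'models.R'
    'inference.R'
    'io.R'
    'simulate.R'
    'workflow.R'
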