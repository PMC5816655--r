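Package: nanosar
Title: Data-Quality Scoring, Gap Filling and Random-Forest Toxicity
    Classification for Metal Oxide Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A meta-analysis pipeline for literature-curated cytotoxicity data
    on metal oxide nanoparticles. Provides a physicochemical data-quality
    scoring framework (0-5 per record from data-source and measurement-method
    provenance), rule-based gap filling of missing physicochemical values via
    manufacturer catalogs, reference lookups and the surface-area/diameter
    relation SSA = 6/(d*rho), score-based screening into quality tiers,
    random-forest classification of a Toxic/Nontoxic viability endpoint with
    replicated 60/40 validation, k-nearest-neighbour applicability-domain
    analysis with a distance cutoff Dc = Dbar + Z*s, leave-one-out
    out-of-bag attribute importance, and a synthetic-data generator that
    emulates the statistical structure of literature-curated nanotoxicity
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
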