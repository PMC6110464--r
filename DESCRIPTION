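Package: SeasonalNiche
Title: Seasonal Grinnellian Niche Modelling for Migratory Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-only ecological niche modelling across the seasons of a
    migratory bird's annual cycle. Fits genetic-algorithm rule-set ensembles
    per season with best-subsets selection, evaluates them with partial ROC
    AUC ratios, characterises internal niche structure by distance to the
    standardized niche centroid (optimal, suboptimal and marginal zones),
    measures niche breadth and overlap with alpha-hulls in a polar-coordinate
    climate space, and tests between-season niche similarity with Schoener's D
    against a record-randomization null in a PCA environment space. Ships a
    synthetic climate and occurrence generator with known ground-truth niche
    structure so the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, MASS, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'geodata-io.R'
    'synthetic-data.R'
    'niche-model.R'
    'model-evaluation.R'
    'niche-structure.R'
    'niche-breadth.R'
    'niche-similarity.R'
    'pipeline.R'
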