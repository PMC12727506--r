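Package: biimapr
Title: Expert-Based Biodiversity Intactness Index Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute the Biodiversity Intactness Index (BII) from
    expert-elicited intactness scores, land-use maps and species richness
    tables. Aggregates per-expert intactness scores into means with 95%
    confidence bounds, allocates pixels to broad land-use classes with a
    priority decision tree, derives continuous land-use intensity from
    minmax-scaled pressure proxies, computes richness-weighted per-pixel BII
    with uncertainty bounds, summarises BII over zones, decomposes remaining
    and lost intactness by land use and intensity stratum, and provides the
    corroboration statistics (rank correlations against external pressure
    indices, hotspot comparisons and a mixed-effects threat-category model).
    A synthetic-data module generates expert score tables, landscapes and
    species records with known ground truth so the whole pipeline can be run
    and verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    lme4,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
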