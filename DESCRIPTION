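Package: morbnet
Title: Temporal Multimorbidity Disease Networks from Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sex- and age-stratified directed disease networks from
    person-level disease-incidence extracts. Directed links between chronic
    conditions are weighted by pair prevalence or by lift (observed/expected
    ratio), filtered by a direction-exclusive exact binomial test with
    Bonferroni control and a lift > 1 rule, and summarised with network and
    node metrics. Overlapping disease clusters are detected by link-community
    analysis (Tanimoto link similarity, Ward linkage, Calinski-Harabasz cut)
    and cluster prevalence is computed under a strict temporal-membership
    rule with small-cell suppression. A synthetic longitudinal cohort
    generator with plantable directed disease associations supports testing
    and method calibration without access to restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
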