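Package: rulemapper
Title: Association-Rule Mining and Mapper Graphs for Claims-Based Patient Journeys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying patient journeys in longitudinal health-claims
    data. Extracts an index-diagnosis cohort (e.g. first ICD-10 F32 claim),
    binarizes pre- and post-onset diagnosis histories, mines pairwise
    association rules (Apriori frequent pairs with support, confidence and
    lift), performs a stratified second-stage analysis of post-onset
    complications within the subset defined by a pre-onset rule, and
    summarizes the rule-index space (support, confidence, lift) with a
    TDA Mapper built from first principles: overlapping interval cover over
    a filter value, single-linkage clustering with a histogram-gap cut in
    each interval, and the nerve graph of the resulting clusters. A
    synthetic claims generator with planted pairwise co-occurrence structure
    provides ground truth for testing every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    graphics,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
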