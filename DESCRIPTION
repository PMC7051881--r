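Package: immunochemo
Title: Co-Occurrence and Association of Immunotherapy and Chemotherapy
    Response Biomarkers
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls immunotherapy-response biomarkers (microsatellite
    instability status from altered microsatellite locus counts, tumor
    mutational burden class from somatic mutation counts, and protein
    marker status from immunohistochemistry scores) from panel-level
    inputs; tests their association with chemotherapy-response protein
    markers using a Breslow-Day-gated Mantel-Haenszel / per-stratum
    Fisher exact procedure stratified by tumor type; and translates
    significant associations into chemotherapy-immunotherapy
    combination-benefit verdicts.  A synthetic-cohort generator with
    configurable marginal prevalences, pairwise odds ratios and
    per-marker testing fractions supports validation of every stage
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
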