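Package: ppipanel
Title: Hub-Bottleneck Screening of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds confidence-filtered protein-protein interaction networks
    from STRING-style exported tables, computes degree, betweenness (Brandes
    accumulation) and closeness centralities, screens hub-bottleneck nodes by
    dual degree/betweenness thresholds, extracts the induced panel subnetwork,
    and performs ClueGO-style annotation-term enrichment (hypergeometric test,
    attribution-percentage filters, kappa-based term grouping). Includes a
    planted-hub synthetic network generator so every pipeline stage can be
    exercised and validated without external database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
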