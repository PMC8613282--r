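Package: replistress
Title: Replication-Stress Response Analysis for ATR Inhibitor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterising cellular and in-vivo responses
    to ATR (ataxia telangiectasia and Rad3-related kinase) inhibition in
    oncogene-driven tumours such as neuroblastoma. Implements differential
    expression and phosphorylation testing with a hyperbolic volcano-plot
    significance threshold, S/TQ (PIKK substrate) phosphosite motif
    classification and position-specific enrichment, preranked and Fisher-based
    gene-set enrichment, extraction of high-confidence first-degree interaction
    subnetworks, and pharmacodynamic summaries (four-parameter logistic IC50
    fitting, Chou-Talalay combination indexes, caliper tumour volumes and
    tumour growth inhibition). A synthetic-data module generates all input
    types with planted ground truth so the full pipeline runs and is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    minpack.lm,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
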