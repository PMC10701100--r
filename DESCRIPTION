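Package: degronr
Title: Degron Discovery, Mutation Annotation and Drug-Resistance Calling in Protein Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for the ubiquitin-proteasome degradation signal (degron)
    landscape of a proteome: consensus-motif scanning with an auditable
    ELM-style pattern grammar, multimodal feature aggregation over per-residue
    annotation tracks, a bootstrapped gradient-boosting ensemble that scores
    motif matches as probable degrons, rule-based functional classification of
    missense mutations falling in or near degrons, a normalized mutation-impact
    score, group-wise IC50 comparison for degron-linked drug resistance, and a
    fully synthetic fixture generator with ground-truth manifests so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
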