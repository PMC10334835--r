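Package: chpf
Title: Cellular Hypoxia Predicting Framework for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a hypoxia status (hypoxic or normoxic) to every cell in a
    single-cell RNA-seq dataset. Per-cell activity scores for a panel of
    hypoxia gene signatures are computed by single-sample gene set enrichment
    analysis (ssGSEA); a two-component Gaussian mixture model per signature
    and a strict all-signature consensus nominate high-confidence hypoxic and
    normoxic cells; the remaining cells are classified by a recall-weighted
    ensemble of gradient-boosted tree classifiers trained on balanced
    undersamples of the high-confidence cells. Also provides the downstream
    critical-regulator ranking (five network centralities integrated by a
    joint order-statistic Q statistic over cell-status-specific gene
    regulatory networks) and small scoring utilities: hypoxia score, copy
    number alteration score, prognostic risk score with median split, weighted
    connectivity score (WTCS), and a drug-transcription-factor association
    filter. A deterministic synthetic-data generator produces every input the
    framework needs, so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
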