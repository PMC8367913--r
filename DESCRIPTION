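Package: mtlogp
Title: Multitask Directed Message Passing Neural Networks for
    Lipophilicity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains directed message-passing neural networks (D-MPNNs)
    jointly on several lipophilicity endpoints (logP, logD7.4) and on
    auxiliary "helper" tasks such as the predictions of other models.
    Provides similarity-biased test-set construction with Tanimoto
    leakage filtering, scaffold-balanced and random splits, ensembles
    with per-compound standard-error-of-the-mean uncertainty, masked
    multitask losses for sparse label matrices, bootstrap confidence
    intervals for regression metrics, matched-pair lipophilicity shift
    analysis, and a synthetic additive-logP benchmark generator for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
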