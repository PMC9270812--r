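Package: ugtsom
Title: Substrate Classification and Site-of-Glucuronidation Prediction for
    UGT-Mediated Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a drug-like molecule is a substrate of
    UDP-glucuronosyltransferases (UGTs) and ranks its candidate sites of
    glucuronidation. Substrate classification uses a soft-voting consensus
    over fingerprint-, descriptor- and graph-based classifiers selected by
    cross-validated Matthews correlation. Site-of-metabolism ranking uses a
    Weisfeiler-Lehman graph network with global attention that scores the
    reactivity of each nucleophilic site against the glucuronosyl anomeric
    carbon, trained on atom-mapped glucuronidation reaction SMIRKS. Includes
    parsers for atom-mapped reactions, a glucuronidation-specific atom
    mapper, molecular featurization (fingerprints, 2D descriptors, graph
    one-hot encodings), ranking and classification metrics, and a synthetic
    benchmark generator with planted structural rules and known sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    randomForest,
    ranger,
    e1071,
    glmnet,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
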