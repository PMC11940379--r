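Package: walkmda
Title: miRNA-Disease Association Prediction with Random-Walk Graph
    Embeddings and a Deep Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a bipartite
    list of validated associations. Builds miRNA and disease similarity
    networks by fusing Gaussian interaction profile (GIP) kernel similarity
    with curated miRNA functional similarity and ontology-DAG disease
    semantic similarity, embeds each network with truncated random walks
    and a skip-gram model (DeepWalk), and classifies miRNA-disease pairs
    with a small feed-forward neural network trained on the concatenated
    node embeddings. Ships global and local leave-one-out cross-validation
    frameworks with ranking metrics (AUC, AUPRC, ACC, MCC) and a
    planted-block synthetic data generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
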