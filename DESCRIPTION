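Package: tknet
Title: Transkingdom Network Inference and Keystone Microbe Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative host-microbiome network analysis: correlation-based
    transkingdom and multi-omic network inference with reproducibility,
    meta-analysis and causality filters; bipartite betweenness centrality
    (BiBC) for ranking microbial and gene candidates that link the microbiota
    to host metabolic phenotypes; generalized Lotka-Volterra community
    simulation with species-removal keystoneness scoring and a linear
    keystoneness predictor trained on simulated communities; plus the
    supporting count preprocessing (cumulative-abundance filtering, cumulative
    sum scaling, quantile normalization) and phenotype derivations (HOMA-IR,
    HOMA-B, glucose tolerance AUC). A synthetic-study generator with planted
    ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    limma,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
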