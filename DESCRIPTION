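Package: retroranker
Title: Re-Ranking Single-Step Retrosynthesis Predictions with Reaction-Change Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven single-step retrosynthesis models rank candidate
    reactant sets for a target product, but their rankings inherit the
    frequency bias of the training reactions: recorded reactants of rare
    reaction patterns land at low ranks with near-tied confidence scores.
    This package scores each (candidate reactants, product) pair with a twin
    graph-neural-network reaction encoder driven by molecular features and
    potential-reaction-change features (reaction center, changed bonds,
    leaving groups, reacted neighborhoods) derived from atom-mapped reaction
    SMILES, trains the scorer with a pairwise label-smoothed cross-entropy
    objective, and re-orders low-confidence predictions with two
    parameterized strategies, S1(p, k) and S2(p, k). Includes parsing and
    serialization of atom-mapped reaction SMILES, top-k accuracy and
    final-accuracy-position evaluation, grid search over re-ranking
    parameters, and a seeded generator of synthetic atom-mapped
    retrosynthesis prediction lists with controllable frequency bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
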