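Package: clonetree
Title: Bayesian Reconstruction of Clonal Phylogenies from Multi-Sample Bulk Sequencing
Version: 0.1.0
Authors@R:
    person("clonetree", "developers", email = "clonetree@example.org", role = c("aut", "cre"))
Description: Infers clonal phylogenies of tumours from multi-sample bulk-sequencing
    allele counts. Mutations are clustered and related by a forest-structured
    Chinese restaurant process prior; clonal prevalences are marginalized on a
    discrete grid by a dynamic program over the tree, and posterior inference over
    tree topologies is performed with a particle Gibbs sampler (conditional
    sequential Monte Carlo with an auxiliary data-ordering variable) plus
    subtree prune-regraft and node-reassignment moves. An explicit outlier state
    accommodates mutations lost to sub-clonal deletions. Ships a synthetic-data
    generator (forest CRP and tree-structured stick-breaking priors, with
    mutation-loss injection) and standard evaluation metrics (V-measure,
    ancestor-descendant F-score, log perplexity ratio, relationship
    reconstruction error).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
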