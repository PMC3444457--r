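Package: ctrnnet
Title: Dynamic Gene Regulatory Network Inference from Short Time-Course
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns short, irregularly sampled time-series expression profiles
    into a signed dynamic gene regulatory network and a ranked list of master
    regulators. The pipeline chains a random-variance-model (RVM) F-test for
    differential expression across time groups, clustering of differential
    genes into discretized temporal-tendency templates with permutation
    significance, gene-set over-representation analysis (Fisher's exact test,
    chi-squared test, enrichment ratio Re and a comparative Fisher-vs-chi2
    false discovery rate), and a continuous-time recurrent neural network
    (CTRNN) dynamic model whose weights, time constants and offsets are
    estimated by a genetic algorithm. Fitted weights are read as signed
    activation/inhibition edges, annotated with database or computed
    provenance against a prior interaction catalog, and summarized into
    regulator rankings and weakly connected sub-networks. A synthetic-data
    module generates ground-truth CTRNN networks and matched annotations so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
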