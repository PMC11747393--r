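Package: conceptgraph
Title: Concept-Graph Analysis of Pairwise Similarity Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing pairwise concept similarity judgments as
    weighted concept graphs. Ratings on the -7..+7 pairwise rating scale are
    rescaled to edge weights, group differences in edge weights are tested
    with edge-wise permutation general linear models under
    Benjamini-Hochberg false-discovery-rate control, across-participant
    Shannon entropy of each concept pair is related to news-bias effect
    magnitude through an offset sigmoid fit, and group effects are
    decomposed into direct and news-bias-mediated paths with Sobel and
    permutation inference. A synthetic cohort generator with planted group,
    mediation, and covariate effects makes every stage testable without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    igraph
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
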