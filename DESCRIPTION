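Package: geolot
Title: Bayesian Validation of Grammar Productions for a Language of Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic program induction over a "language of
    geometry": a context-free grammar whose programs describe movement
    sequences on the eight labelled vertices of a regular octagon. The
    package enumerates, by exact dynamic programming, every derivation tree
    that explains an observed point sequence; infers per-production
    probabilities of the probabilistic grammar by Gibbs sampling with a
    conjugate Dirichlet prior; computes the minimum-description-length
    complexity of a sequence and its (unnormalised) algorithmic probability;
    and empirically tests the Coding-Theorem style inverse relation between
    the two. A synthetic-data generator produces trial datasets with the
    statistical structure the inference assumes, standing in for behavioural
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
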