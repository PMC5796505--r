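Package: parsboot
Title: Maximum Parsimony Tree Search with a Fast Bootstrap Approximation
Version: 0.1.0
Authors@R: person("Parsboot", "Developers", email = "parsboot@example.org",
    role = c("aut", "cre"))
Description: Maximum parsimony phylogenetic inference for DNA and protein
    alignments under uniform and non-uniform (step matrix) substitution
    costs, with Fitch and Sankoff per-pattern scoring, randomized stepwise
    addition, SPR hill climbing and the parsimony ratchet.  Branch supports
    are obtained by a fast bootstrap approximation that rescores trees
    sampled on the original alignment against every bootstrap replicate via
    weighted sums of per-pattern scores, followed by a per-replicate
    refinement step, support mapping and majority-rule consensus.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
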