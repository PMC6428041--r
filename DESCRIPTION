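Package: contactpcfg
Title: Probabilistic Context-Free Grammars for Protein Motifs with Contact-Map Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation and application of probabilistic context-free grammars
    (PCFG) for families of protein motif sequences, using partial residue-residue
    contact maps as constraints on the shape of syntactic trees. Implements
    grammars in Chomsky Normal Form extended with contact rules, a
    contact-constrained probabilistic CKY chart parser (inside probabilities,
    skeleton mass, most-likely parse trees), maximum-likelihood and contrastive
    training objectives optimised by a Pittsburgh-style genetic algorithm,
    discriminative scoring against a unigram null model, descriptive
    (contact-prediction) evaluation of parse trees, sliding-window motif search,
    and generative simulation of synthetic sequence/contact-map benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
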