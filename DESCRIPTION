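Package: hennigforest
Title: Matrix-Free Cladistics with Hennigian Forests and Average Consensus
Version: 0.1.0
Authors@R:
    person("Forest", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rewrites binary character matrices as forests of rooted trees
    ("Hennigian forests"), one tree per character with clades based solely on
    the apomorphic state, and analyses the forest with the Average Consensus
    supertree method: unit-branch-length path-distance tables averaged over
    the forest, followed by least-squares (OLS/WLS), neighbor-joining,
    balanced minimum evolution or UPGMA tree estimation. Includes the
    supporting recoders (presence/absence recoding of DNA alignments,
    additive binary recoding of ordered multistate characters, artificial
    all-zero outgroups), a Fitch/Wagner parsimony scorer with ensemble
    consistency and retention indices for verification, and deterministic
    synthetic-data generators for tree-derived matrices, reversal
    perturbations and homoplasy-free DNA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
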