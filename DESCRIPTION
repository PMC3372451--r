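Package: spliceforest
Title: Parsimony Reconstruction of Transcript Phylogenies on Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the evolution of alternatively spliced transcripts as a
    two-level process: exons are gained, lost, or switch between alternative
    and constitutive status along a known gene tree, while transcripts gain
    and lose exons, die, and are born on top of the evolving gene structure.
    Reconstructs ancestral exon states under Dollo parsimony with Sankoff's
    small-parsimony algorithm, then searches the space of transcript-forest
    topologies with lower-bound pruning and a guide-tree-constrained dynamic
    program for the leaf assignment, returning every minimum-cost forest of
    transcript trees. Includes a synthetic-instance simulator, a brute-force
    oracle for validation, benchmark utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
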