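Package: mutselshift
Title: Non-Equilibrium Mutation-Selection Codon Models and Detection of
    Selective Shifts on Phylogenies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits non-reversible mutation-selection codon substitution
    models on fixed rooted phylogenies and infers the number and branch
    positions of sequence-wide shifts in amino-acid fitness profiles by a
    greedy AICc-guided search.  The substitution process couples an HKY
    mutation layer with the Wright-Fisher diffusion fixation probability
    evaluated without log-linearisation, which makes the 61x61 codon
    generator asymmetric and the process non-time-reversible.  Includes a
    branch-heterogeneous pruning likelihood with free or equilibrium root
    codon frequencies, maximum-likelihood fitting, a simulator for codon
    alignments on random birth trees with controlled balance, and scoring
    utilities for simulation studies of shift detection and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minqa,
    stats,
    tibble,
    utils
Suggests:
    expm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
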