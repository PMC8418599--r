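Package: seminet
Title: Distinguishability of Level-1 Semi-Directed Phylogenetic Networks
    under Group-Based Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with triangle-free level-1 semi-directed
    phylogenetic networks and the group-based DNA substitution models
    (Jukes-Cantor, Kimura 2-parameter, Kimura 3-parameter) defined on them.
    Parses extended Newick, computes splits, restrictions, quotients and
    cycle partitions, enumerates the 4-leaf network catalog, simulates
    site-pattern distributions by marginalisation over displayed trees,
    parameterises models in Fourier (Hadamard) coordinates, evaluates
    phylogenetic invariants exactly, and runs a recursive certificate
    search that decides, for a pair of networks, whether the variety of
    one model is contained in the other's - the computational core of
    generic identifiability for this network class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
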