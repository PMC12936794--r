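Package: tangleasm
Title: Pangenome-Guided Sequence Assembly by Binary Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Resolves tangled regions of pangenome graphs into assembled
    sequence by casting walk finding as a Quadratic Unconstrained Binary
    Optimization (QUBO) problem. Reads and writes GFA 1.0 graphs, annotates
    nodes with copy-number estimates from k-mer hits of short reads,
    encodes plain, oriented and diploid tangle-resolution problems with
    time-indexed binary variables and Lagrange penalties, solves them with
    exhaustive enumeration, simulated annealing or multistart tabu search,
    and simulates the CVaR-QAOA loop on the equivalent diagonal
    Hamiltonian. A synthetic-data module generates genome populations,
    shotgun reads and graph instances with known ground truth, and an
    evaluation module scores candidate assemblies against the truth with
    standard contiguity and accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
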