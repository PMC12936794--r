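# tangleasm

Pangenome-guided sequence assembly by binary optimization.

Short-read assembly through the repeat-dense, tangled regions of a
pangenome graph is hard because reads alone do not say how often, or
in which order, the target genome traverses each node. `tangleasm` is
an R package for resolving such regions: it annotates graph nodes with
copy-number estimates from unique k-mer hits of the reads, then finds
the walk whose visit counts best explain those estimates by minimizing

    C_G(W) = sum_v ( #W(v) - w(v) )^2

over walks `W` on the graph — where `#W(v)` counts visits of node `v`
(both orientations combined in the oriented variant, summed over a
pair of walks in the diploid variant) and `w(v)` is the estimated copy
number. The search is encoded as a Quadratic Unconstrained Binary
Optimization (QUBO) with time-indexed variables `x[t,v]`, a virtual
end node, and Lagrange penalties `Λ1 = 10`, `Λ2 = 5` enforcing
one-site-per-time and edge-following constraints over a horizon
`T = ceil(α Σ round(w))`, `α = 1.2`. The QUBO is minimized by
exhaustive enumeration, simulated annealing, or multistart tabu
search, or handed to a classically simulated CVaR-QAOA loop (diagonal
cost Hamiltonian via the `(I − Z)/2` substitution, `p` alternating
cost/mixer layers, shot-sampled conditional-value-at-risk objective).
Decoded walks become contig sequences that are scored against a known
truth with the standard contiguity and accuracy metrics, and a
synthetic-data module (genome populations, shotgun reads, graph
instances with known ground truth) makes the whole pipeline
self-contained.

The intended audience is researchers in assembly methods and in
combinatorial/quantum optimization who want a small, fully
reproducible, oracle-checked implementation of this pipeline.

## A worked example

The canonical zero-copy situation: a line graph `A→B→C→D→E` whose
estimated copy numbers are `(1, 1, 0, 1, 1)` — node `C` looks absent
from the target. A prescriptive decomposition (delete zero-copy nodes,
report the remaining runs) must split the region; the cost function
happily pays one squared unit to pass through `C` and keep the region
whole:

```r
library(tangleasm)
set.seed(1)
g <- annotated_graph(
  data.frame(id = LETTERS[1:5],
             seq = vapply(rep(60, 5), random_dna, character(1)),
             weight = c(1, 1, 0, 1, 1)),
  data.frame(from = LETTERS[1:4], from_orient = "+",
             to = LETTERS[2:5], to_orient = "+"))

length(prescriptive_decompose(g))
#> [1] 2                      # the baseline reports A-B and D-E

inst <- build_qubo(g, "plain")   # T = ceil(1.2 * 4) = 5, 30 variables
sol  <- solve_and_decode(inst, method = "tabu", seed = 1)
sol$result$best_energy
#> [1] 1                      # = walk cost of the optimum
contigs <- sol$decoded$walks[[1]]
paste(contigs[[1]]$node, collapse = "")
#> [1] "ABCDE"                # one unified contig

enumerate_optimum(g, "plain", 5)$cost   # independent brute-force oracle
#> [1] 1
```

The tabu solution's energy 1 is certified by the walk-enumeration
oracle: no walk of length up to 5 does better, and the decoded walk is
the single unified traversal — the qualitative advantage of the
cost-function route over prescriptive splitting.

The same instance, annotated from simulated reads instead of given
weights:

```r
ins   <- make_instance("line", n_nodes = 5, node_length = 300, seed = 9)
reads <- shred_reads(ins$truth_sequence,
                     read_config(coverage = 30, read_length = 150,
                                 sub_error_rate = 0, seed = 4))
ann   <- annotate_graph(ins$graph, reads, k = 31)
round(ann$nodes$weight)
#> [1] 1 1 1 1 1              # rounded estimates recover the truth
```

A command-line front end over the same functions ships in
`exec/tangleasm` (`graph stats`, `annotate`, `qubo build`, `solve`,
`qaoa`, `baseline`, `cost`, `eval`, `polish`).

See `vignettes/tangle-resolution.Rmd` for the model, the encoding, the
solver and QAOA design choices, the synthetic-data generator's
assumptions, and known limitations.

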