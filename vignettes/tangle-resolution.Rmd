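---
title: "Tangle resolution: pangenome-guided assembly as binary optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tangle resolution: pangenome-guided assembly as binary optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tangleasm)
```

## The problem

A pangenome graph represents the sequence variation of a population:
nodes are DNA fragments, oriented edges are adjacencies observed in at
least one genome. Reconstructing a new individual's sequence from
short reads against such a graph avoids the reference bias of a single
linear reference, but in repeat-dense, tangled regions the reads alone
cannot say how often and in which order the target genome traverses
each node. `tangleasm` resolves such regions in three stages:

1. **Annotation.** Count unique k-mer hits of the reads on each node
   and depth-normalize them into a per-node copy-number estimate
   $w(v) \ge 0$.
2. **Walk finding.** Find a walk $W$ on the graph whose visit counts
   best explain the estimates, by minimizing the tangle-resolution cost
   $$C_G(W) = \sum_{v} \bigl(\#W(v) - w(v)\bigr)^2 ,$$
   where $\#W(v)$ counts visits of $v$ (both orientations combined in
   the oriented variant; summed over both walks of a pair in the
   diploid variant).
3. **Evaluation.** Spell the walk into sequence, optionally polish it
   with a read consensus, and score it against a known truth.

The squared-deviation cost is the essential difference from a
*prescriptive* decomposition, which deletes every node whose rounded
copy number is zero and reports the remaining connected runs as
contigs. A noisy or genuinely-zero estimate in the middle of a region
then forcibly splits the assembly. The cost function instead lets the
walk pass through a zero-weight node at a price of one squared unit
when doing so joins two otherwise well-supported runs; robustness to
copy-number noise is the design goal. `prescriptive_decompose()`
implements the baseline behaviour for comparison.

```{r worked-example}
set.seed(1)
g <- annotated_graph(
  data.frame(id = LETTERS[1:5],
             seq = vapply(rep(60, 5), random_dna, character(1)),
             weight = c(1, 1, 0, 1, 1)),
  data.frame(from = LETTERS[1:4], from_orient = "+",
             to = LETTERS[2:5], to_orient = "+"))
length(prescriptive_decompose(g))        # the baseline splits: 2 contigs
enumerate_optimum(g, "plain", 5)$cost    # the unified walk costs only 1
```

## The QUBO encoding

Walk finding is NP-hard in general (it generalizes Hamiltonian path),
so the search is encoded as a Quadratic Unconstrained Binary
Optimization in the style of time-indexed travelling-salesman
encodings. Binary variable $x_{t,v}$ is 1 when the walk sits at site
$v$ at time $t \in \{1..T\}$; sites are the graph's nodes (both
orientations in the oriented variant) plus a virtual **end node** with
no sequence, which absorbs the walk once it finishes. The full cost is

$$C = \Lambda_1 \sum_t \Bigl(\sum_v x_{t,v} - 1\Bigr)^2
    + \Lambda_2 \sum_t \Bigl[\; \text{non-edge transitions} +
      \text{transitions leaving end} \;\Bigr]
    + \sum_v \Bigl(\sum_t x_{t,v} - w(v)\Bigr)^2 .$$

`build_qubo()` expands this into a symmetric coefficient matrix plus a
constant offset, so that `qubo_energy()` of any bit vector equals
$C^1 + C^2 + C^3$ exactly; for every valid walk,
`qubo_energy(encode_walk(W))` equals `walk_cost(W)` to machine
precision (the penalties vanish), a property the test suite checks
exhaustively on small graphs.

Key parameters, all exposed on `build_qubo()`:

* **Horizon** `T = ceiling(alpha * sum(round(w)))` with `alpha = 1.2`
  by default: the walk may use up to 20% more steps than the copy
  numbers suggest, leaving room to over-visit a node when that
  substantially improves the rest of the solution. `T_override`
  bypasses the rule (useful for reduced-size exhaustive checks).
* **Penalties** `lambda1 = 10`, `lambda2 = 5`: large enough that the
  optimizer respects the one-site-per-time and edge constraints, small
  enough that the data term still shapes the landscape. With accurate
  copy numbers the data term steers the solution; with very noisy ones
  the penalties dominate and at least enforce a structurally valid
  walk.
* **End-node dynamics**: staying at the end and *entering* it are
  free; only transitions that *leave* the end node pay `lambda2`. An
  optimal assignment therefore parks at the end once the walk is done.
  The decoder (`decode_assignment()`) is nevertheless total: it splits
  imperfect assignments into maximal valid sub-walks at end visits and
  non-edge transitions, and reports every irregularity it had to
  resolve.

Variable counts are $(N{+}1)T$ for the plain variant, $(2N{+}1)T$ for
oriented and $2(2N{+}1)T$ for diploid (the two haplotype walks carry
independent constraint terms but share one data term).

## Solvers

Three classical solvers operate on the same local-field bookkeeping
($O(n)$ per bit flip; no full-matrix re-evaluation inside search
loops):

* `solve_exhaustive()` enumerates all $2^n$ assignments (capped at
  $n \le 24$) and is the oracle for everything else.
* `solve_anneal()` is single-flip Metropolis under a geometric inverse
  temperature schedule (0.1 to 10 over 2000 sweeps by default).
* `solve_tabu()` is a multistart tabu search: steepest-descent single
  flips, a recency tabu list (tenure `max(10, n/10)`) with the usual
  best-ever aspiration, restarts after 500 non-improving moves. This
  is the workhorse; it matches the exhaustive optimum on essentially
  all test instances at the sizes exercised here.

All solvers are deterministic for a fixed seed (tabu only when no
wall-clock limit is set, since time checks depend on the machine).

## Simulated CVaR-QAOA

`hamiltonian_from_qubo()` maps the QUBO to a diagonal Hamiltonian by
the standard $(I - Z)/2$ substitution, so basis state $|b\rangle$ has
energy equal to the cost of assignment $b$. `qaoa_statevector()`
simulates the circuit — a Hadamard layer, then $p$ alternating cost
phases $e^{-i\gamma H}$ and mixer layers $e^{-i\beta \sum_i X_i}$ —
as a dense statevector (capped at 20 qubits), applying the mixer one
qubit axis at a time.

`run_qaoa()` closes the loop: at each iteration the exact output
distribution is sampled (`shots = 256` by default, the only noise
modelled), and the **CVaR** of the sampled energies — the mean of the
best `cvar_alpha` fraction (default 0.1) — is handed to a
derivative-free Nelder-Mead search over $(\gamma, \beta)$. Two
numerical choices matter and were settled empirically:

* The simplex search is **restarted from fresh random angles every 25
  iterations** rather than run once to the iteration budget. The CVaR
  objective is evaluated from a finite sample and is therefore noisy;
  a single long descent reliably stalls in a noise-induced basin,
  while many short probes find parameter regions that concentrate
  probability on low-energy states. On the 10-qubit oriented instance
  used in the tests this is the difference between sampling the global
  optimum in roughly two-thirds versus nearly all seeded runs.
* Initial angles are uniform in $(0, 0.1\pi)$; a linear-ramp
  initialization is available via `init = "ramp"`.

The CVaR fraction 0.1 and the choice of Nelder-Mead are this package's
defaults; the method itself does not prescribe them. Shot sampling is
the only noise source — gate noise, hardware execution and error
mitigation are out of scope.

## Copy-number annotation

`index_graph()` (default `k = 31`, the conventional assembly choice)
records each node's canonical k-mers — the lexicographic minimum of a
k-mer and its reverse complement, which makes counting strand-blind —
and each node's **unique fraction**: the share of its k-mer positions
owned by no other node. `count_hits()` increments a node only for read
k-mers owned by that node alone; k-mers shared between nodes are
dropped entirely (the deterministic analogue of discarding secondary
alignments) rather than fractionally assigned.

`estimate_copy_numbers()` turns counts into weights:
$d(v) = \text{counts}(v) / n_{\text{unique}}(v)$ is the observed depth
per expected unique k-mer position; the per-copy depth $D$ is the
node-length-weighted **median** of $d(v)$ over nodes with unique
fraction at least 0.5 and non-zero depth; the weight is $d(v)/D$.
The median (rather than the mean) resists repeat-inflated nodes, and
excluding zero-depth nodes keeps the estimator sane when much of the
graph is simply absent from the target genome, the expected situation
for a diverged individual. Nodes with unique fraction zero cannot be
measured at all and carry a `-1` "unknown" sentinel in memory (their
`CN` tag is omitted on disk). The division by the unique fraction is
this package's stand-in for a hit-rate expectation; it assumes hits
are lost uniformly across a node's positions.

The estimator presumes that single-copy nodes dominate the
length-weighted depth distribution. When the majority of the sequence
in a region is multi-copy, the median lands on the repeat depth and
all estimates halve; that regime is outside the estimator's contract.

## The synthetic-data generator

The generator makes the pipeline self-contained, emulating the
problem-creation stage of the study design:

* `generate_population()` grows a population (default 100 genomes over
  10 generations) from a random founder. Each descendant derives from
  one randomly chosen earlier genome and mutates at a reduced rate
  (`descendant_rate_factor = 0.1`). Mutation classes: short-tandem
  expansions (2-6 bp unit), tandem CNVs (100-1000 bp), insertions of
  fixed 50 bp / 500 bp library elements, cut-and-paste translocations,
  in-place inversions (reverse complement), and per-base point
  substitutions. The structural classes draw Poisson event counts per
  genome; points are i.i.d. Bernoulli per base. The default founder
  rates (3e-4, 1e-4, 2e-4, 5e-5, 5e-5, 5e-5 events/base and 0.002
  substitutions/base on a 10 kb founder) were chosen once to give a
  handful of structural events per founder at this scale; the method's
  source material does not fix them.
* `shred_reads()` draws `round(coverage * L / read_length)` single-end
  reads (defaults: 30-fold, 150 bp, substitution-error rate 0.005)
  with uniform start positions and strands; substitution errors only,
  no indels, constant quality. Linear genomes therefore have a
  coverage ramp over the first and last read length, which depresses
  depth — and hence copy-number estimates — at the outermost nodes by
  up to ~20% of a copy; integer rounding absorbs this in practice.
* `make_instance()` builds graph instances with known truth: `line`,
  `cycle`, `tangle` (a line with a back edge whose repeated stretch is
  capped at a third of the nodes, so single-copy sequence dominates as
  it does in real pangenome tangles) and `random` shapes. Noiseless
  weights equal the truth walk's visit counts exactly; optional
  Gaussian weight noise is truncated at zero and rounded to one
  decimal. `skip_nodes` marks nodes absent from the target genome
  (weight 0, truth split into valid sub-walks) — the zero-copy
  situation of the worked example above.

What the generator does **not** emulate: paired-end reads, indel
sequencing errors, quality-score structure, realistic repeat-family
evolution, diploid phasing structure, and graphs built by an actual
pangenome constructor from the simulated population (instances are
generated directly with known truth instead). Tests passing on these
instances demonstrate the optimization and evaluation machinery, not
performance on real pangenome graphs.

## Evaluation

`walk_to_sequence()` concatenates node sequences, reverse-complementing
"-" steps. `align_blocks()` aligns candidate contigs to the truth with
unique-k-mer anchors (21-mers occurring exactly once in each sequence,
both strands), chains them into the longest co-linear, strand-consistent
chain with gaps capped at 500 bp, and fills inter-anchor gaps by global
pairwise alignment. Gap penalties are deliberately stiff (opening 10,
extension 10 against match +1 / mismatch -1): between exact anchors, a
length difference is a real indel, while equal-length divergence should
align column-on-column as substitutions instead of dissolving into
spurious gap pairs that hide divergent regions. Each contig region is
assigned to at most one block (best chain first). On the small, unique
synthetic genomes used here this fully replaces a general-purpose
mapper and is deterministic.

`evaluate_assembly()` reports the eight metrics: %covered (truth bases
under some block), %used (contig bases under some block), number of
contigs, N50, breaks (per contig, one less than its block count — a
false-join proxy), indel events of at least 10 bases (events, not
bases), difference regions (fixed non-overlapping 100 bp truth windows
with at least 30 mismatching columns), and percent identity (matches
over aligned columns). Break and indel counting rules are this
package's operationalizations; the metrics they approximate are
usually derived from mapper flags, which are not specified at this
level of detail.

`consensus_polish()` places reads on the candidate by unique-anchor
offset voting and substitutes majority bases in columns covered by at
least 3 reads (no indel edits, ties keep the original base).

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately small
scale, chosen so exhaustive oracles stay exact: graphs of up to 8
nodes, QUBO instances up to 24 variables for exhaustive enumeration
and up to ~170 for tabu search, QAOA at 10 qubits, genomes of a few
kilobases at 30-fold coverage. Every stochastic component takes an
explicit seed and restores the caller's RNG state; identical seeds
give bitwise-identical populations, reads, instances, solver runs and
QAOA runs.

## Known limitations

* Edge weights (traversal counts) are not part of any cost function;
  inversions supported only by edge evidence can therefore be missed.
* Polyploidy beyond two haplotypes is not modelled.
* The dense statevector limits QAOA simulation to 20 qubits; the dense
  coefficient matrix makes `build_qubo()` quadratic in variable count,
  comfortable at hundreds of variables but not thousands.
* The anchor-chaining aligner assumes unique 21-mers anchor reliably,
  which holds on small synthetic genomes but not on genuinely
  repetitive real sequence at scale.
* `read_qubo()` recovers the coefficient matrix only; decoding back to
  walks needs the in-memory instance built by `build_qubo()`.
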