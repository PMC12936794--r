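test_that("canonical k-mer indexing matches hand enumeration", {
  g <- annotated_graph(data.frame(id = "X", seq = "ACGTACGT"))
  idx <- index_graph(g, k = 4)
  # windows: ACGT CGTA GTAC TACG ACGT; canonical forms:
  # ACGT (self-rc), CGTA (rc TACG), GTAC (self-rc), CGTA, ACGT
  expect_equal(sort(idx$node_kmers$X),
               sort(c("ACGT", "ACGT", "CGTA", "CGTA", "GTAC")))
  expect_equal(unname(idx$n_kmers["X"]), 5)
  expect_equal(unname(idx$unique_fraction["X"]), 1)
})

test_that("unique fractions reflect sharing between nodes", {
  set.seed(1)
  s <- random_dna(60)
  g <- annotated_graph(data.frame(id = c("A", "B"), seq = c(s, s)))
  idx <- index_graph(g, 21)
  expect_equal(unname(idx$unique_fraction), c(0, 0))

  g2 <- annotated_graph(data.frame(id = c("A", "B"),
                                   seq = c(random_dna(60), random_dna(60))))
  idx2 <- index_graph(g2, 21)
  expect_equal(unname(idx2$unique_fraction), c(1, 1))
})

test_that("k-mers containing N are excluded and short nodes rejected", {
  g <- annotated_graph(data.frame(id = "A", seq = "ACGTNACGT"))
  idx <- index_graph(g, 4)
  expect_false(any(grepl("N", idx$node_kmers$A)))
  expect_equal(unname(idx$n_kmers["A"]), 2)  # only 2 N-free windows
  expect_error(index_graph(g, 31), "shorter than k")
  expect_error(index_graph(g, 2), "k must be")
})

test_that("count_hits assigns unique k-mer hits and drops ambiguous ones", {
  set.seed(2)
  sA <- random_dna(50); sB <- random_dna(50)
  g <- annotated_graph(data.frame(id = c("A", "B"), seq = c(sA, sB)))
  idx <- index_graph(g, 21)
  # empty read set
  c0 <- count_hits(idx, character(0))
  expect_equal(unname(c0$counts), c(0, 0))
  # reads copied verbatim from node A: count = number of k windows
  reads <- c(substr(sA, 1, 40), substr(sA, 11, 50))
  cA <- count_hits(idx, reads)
  expect_equal(unname(cA$counts["A"]), 2 * (40 - 21 + 1))
  expect_equal(unname(cA$counts["B"]), 0)
  expect_equal(cA$total_reads, 2)
  # a read matching only a shared k-mer counts nowhere
  shared <- random_dna(21)
  g2 <- annotated_graph(data.frame(
    id = c("A", "B"),
    seq = c(paste0(shared, random_dna(20)), paste0(shared, random_dna(20)))))
  idx2 <- index_graph(g2, 21)
  cS <- count_hits(idx2, shared)
  expect_equal(unname(cS$counts), c(0, 0))
})

test_that("count_hits sees reverse-complement reads through canonicalization", {
  set.seed(3)
  sA <- random_dna(60)
  g <- annotated_graph(data.frame(id = "A", seq = sA))
  idx <- index_graph(g, 21)
  fwd <- count_hits(idx, substr(sA, 1, 50))
  rev <- count_hits(idx, revcomp(substr(sA, 1, 50)))
  expect_equal(fwd$counts, rev$counts)
  expect_gt(unname(fwd$counts["A"]), 0)
})

test_that("copy-number estimation recovers single-copy depth", {
  ins <- make_instance("line", n_nodes = 4, node_length = 400, seed = 31)
  reads <- shred_reads(ins$truth_sequence,
                       read_config(30, 150, 0, seed = 32))
  ann <- annotate_graph(ins$graph, reads, k = 31)
  # ~80 reads cover each 400 bp node, so per-node depth noise is ~11%;
  # end nodes additionally sag from the linear-genome coverage ramp
  expect_true(all(abs(ann$nodes$weight - 1) < 0.35))
  expect_lt(abs(mean(ann$nodes$weight) - 1), 0.15)
})

test_that("a node traversed twice estimates near copy number 2", {
  ins <- make_instance("tangle", n_nodes = 6, node_length = 400, seed = 33)
  reads <- shred_reads(ins$truth_sequence,
                       read_config(30, 150, 0, seed = 34))
  ann <- annotate_graph(ins$graph, reads, k = 31)
  two <- ins$graph$nodes$weight == 2
  expect_true(any(two))
  expect_true(all(abs(ann$nodes$weight[two] - 2) < 0.3))
})

test_that("a single covered node defines the per-copy depth", {
  set.seed(4)
  g <- annotated_graph(data.frame(
    id = c("A", "B", "C"),
    seq = c(random_dna(100), random_dna(100), random_dna(100))))
  idx <- index_graph(g, 21)
  counts <- structure(list(
    counts = setNames(c(240, 0, 0), c("A", "B", "C")),
    total_reads = 10, total_bases = 1000), class = "node_counts")
  ann <- estimate_copy_numbers(g, counts, idx)
  expect_equal(ann$nodes$weight, c(1, 0, 0))
})

test_that("weights are invariant to doubling all counts", {
  set.seed(5)
  g <- annotated_graph(data.frame(
    id = c("A", "B"), seq = c(random_dna(120), random_dna(120))))
  idx <- index_graph(g, 21)
  mk <- function(v) structure(list(counts = setNames(v, c("A", "B")),
                                   total_reads = 1, total_bases = 1),
                              class = "node_counts")
  a <- estimate_copy_numbers(g, mk(c(100, 210)), idx)
  b <- estimate_copy_numbers(g, mk(c(200, 420)), idx)
  expect_equal(a$nodes$weight, b$nodes$weight)
})

test_that("raising a non-median node's count never lowers its weight", {
  set.seed(6)
  g <- annotated_graph(data.frame(
    id = c("A", "B", "C"),
    seq = c(random_dna(150), random_dna(150), random_dna(150))))
  idx <- index_graph(g, 21)
  mk <- function(v) structure(list(counts = setNames(v, c("A", "B", "C")),
                                   total_reads = 1, total_bases = 1),
                              class = "node_counts")
  base <- c(100, 100, 150)
  prev <- -Inf
  for (extra in seq(0, 200, by = 40)) {
    w <- estimate_copy_numbers(g, mk(base + c(0, 0, extra)), idx)
    wc <- w$nodes$weight[3]
    expect_gte(wc, prev)
    prev <- wc
  }
})

test_that("fully repetitive graphs are rejected with advice", {
  set.seed(7)
  s <- random_dna(80)
  g <- annotated_graph(data.frame(id = c("A", "B"), seq = c(s, s)))
  expect_error(annotate_graph(g, substr(s, 1, 40), k = 21), "larger k")
})

test_that("rounded estimates recover true copy numbers on clean reads", {
  ok <- 0; total <- 0
  for (seed in 1:10) {
    shape <- if (seed %% 2 == 0) "tangle" else "line"
    ins <- make_instance(shape, n_nodes = 5, node_length = 350, seed = seed)
    reads <- shred_reads(ins$truth_sequence,
                         read_config(30, 150, 0, seed = seed + 1000))
    idx <- index_graph(ins$graph, 31)
    ann <- estimate_copy_numbers(ins$graph, count_hits(idx, reads), idx)
    elig <- idx$unique_fraction >= 0.5
    total <- total + sum(elig)
    ok <- ok + sum(floor(ann$nodes$weight[elig] + 0.5) ==
                     ins$graph$nodes$weight[elig])
  }
  expect_gte(ok / total, 0.9)
})
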