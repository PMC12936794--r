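test_that("walk_to_sequence concatenates and reverse-complements", {
  g <- annotated_graph(
    data.frame(id = c("A", "B"), seq = c("ACGT", "AAAC")),
    data.frame(from = "A", from_orient = "+", to = "B", to_orient = "-"))
  expect_equal(walk_to_sequence(g, walk(c("A", "B"), c("+", "-"))),
               "ACGTGTTT")
  expect_equal(walk_to_sequence(g, walk("A")), "ACGT")
  expect_equal(walk_to_sequence(g, walk()), "")
  expect_error(walk_to_sequence(g, walk(c("B", "A"), c("-", "-"))),
               "invalid walk")
  # a walk and its orientation-flipped reversal are reverse complements
  w <- walk(c("A", "B"), c("+", "-"))
  wrev <- walk(c("B", "A"), c("+", "-"))
  expect_length(validate_walk(g, wrev), 0)  # closure edge
  expect_equal(walk_to_sequence(g, wrev),
               revcomp(walk_to_sequence(g, w)))
})

test_that("identical and reverse-complement candidates align fully", {
  set.seed(11)
  truth <- random_dna(2000)
  b <- align_blocks(truth, truth)
  expect_equal(nrow(b), 1)
  expect_equal(b$truth_start, 0); expect_equal(b$truth_end, 2000)
  expect_equal(b$n_mismatches + b$n_ins + b$n_del, 0)
  b2 <- align_blocks(revcomp(truth), truth)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$strand, "-")
  expect_equal(b2$n_matches, 2000)
})

test_that("swapping the halves of the truth yields two blocks", {
  set.seed(12)
  truth <- random_dna(2000)
  cand <- paste0(substr(truth, 1001, 2000), substr(truth, 1, 1000))
  b <- align_blocks(cand, truth)
  expect_equal(nrow(b), 2)
  # brute-force exact matching pins the block coordinates
  expect_setequal(b$truth_start, c(0, 1000))
  expect_setequal(b$truth_end, c(1000, 2000))
  expect_setequal(b$contig_start, c(0, 1000))
  expect_equal(sum(b$n_matches), 2000)
})

test_that("no anchors yields an empty block table", {
  set.seed(13)
  b <- align_blocks(random_dna(200), random_dna(200))
  expect_equal(nrow(b), 0)
  expect_error(align_blocks("ACGT", ""), "non-empty")
})

test_that("N50 matches the brute-force prefix-sum definition", {
  expect_equal(n50(c(1, 2, 3, 4)), 3)
  expect_equal(n50(numeric(0)), 0)
  n50_brute <- function(lens) {
    s <- sort(lens, decreasing = TRUE)
    for (i in seq_along(s)) if (sum(s[1:i]) >= sum(s) / 2) return(s[i])
  }
  set.seed(14)
  for (i in 1:20) {
    lens <- sample(1:5000, sample(1:12, 1), replace = TRUE)
    expect_equal(n50(lens), n50_brute(lens))
  }
})

test_that("truth against itself scores perfectly on every metric", {
  set.seed(15)
  truth <- random_dna(1500)
  r <- evaluate_assembly(align_blocks(truth, truth), truth, truth)
  expect_equal(r$covered_pct, 100)
  expect_equal(r$used_pct, 100)
  expect_equal(r$n_contigs, 1)
  expect_equal(r$breaks, 0)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$n50, 1500)
  expect_equal(r$indels_ge10, 0)
  expect_equal(r$diff_regions, 0)
})

test_that("evaluation is invariant to reverse-complementing the candidate", {
  set.seed(16)
  truth <- random_dna(3000)
  cand <- paste0(substr(truth, 1, 1400), random_dna(40),
                 substr(truth, 1441, 3000))  # 40 bp replacement
  fwd <- evaluate_assembly(align_blocks(cand, truth), cand, truth)
  rev <- evaluate_assembly(align_blocks(revcomp(cand), truth),
                           revcomp(cand), truth)
  expect_equal(unclass(fwd), unclass(rev))
})

test_that("partial assemblies report coverage both ways", {
  set.seed(17)
  truth <- random_dna(1000)
  cand <- substr(truth, 1, 600)
  r <- evaluate_assembly(align_blocks(cand, truth), cand, truth)
  expect_equal(r$covered_pct, 60)
  expect_equal(r$used_pct, 100)
})

test_that("large insertions are counted as single gap events", {
  set.seed(18)
  truth <- random_dna(1200)
  cand <- paste0(substr(truth, 1, 600), random_dna(60),
                 substr(truth, 601, 1200))
  b <- align_blocks(cand, truth)
  r <- evaluate_assembly(b, cand, truth)
  expect_equal(nrow(b), 1)          # 60 << max gap: one chained block
  expect_equal(r$breaks, 0)
  expect_equal(r$indels_ge10, 1)    # one event, not 60
  expect_equal(r$covered_pct, 100)
})

test_that("runs of dense mismatches register as difference regions", {
  set.seed(19)
  truth <- random_dna(1200)
  # corrupt 60 of 100 positions in one window far from the block edges
  # (enough that alignment slippage cannot drop the count below 30)
  b <- strsplit(truth, "")[[1]]
  pos <- 601:660
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  cand <- paste(b, collapse = "")
  r <- evaluate_assembly(align_blocks(cand, truth), cand, truth)
  expect_gte(r$diff_regions, 1)
  expect_lt(r$identity_pct, 100)
})

test_that("consensus polishing corrects planted errors and nothing else", {
  set.seed(20)
  truth <- random_dna(1500)
  reads <- shred_reads(truth, read_config(30, 100, 0, seed = 21))
  # error-free reads from the candidate itself leave it unchanged
  expect_equal(consensus_polish(truth, reads), truth)
  # a planted error is corrected back
  cand <- truth
  substr(cand, 700, 700) <- setdiff(c("A", "C", "G", "T"),
                                    substr(truth, 700, 700))[1]
  expect_equal(consensus_polish(cand, reads), truth)
  # no reads: unchanged
  expect_equal(consensus_polish(cand, character(0)), cand)
})

test_that("polishing tolerates sequencing errors in the reads", {
  set.seed(22)
  truth <- random_dna(1500)
  reads <- shred_reads(truth, read_config(30, 100, 0.01, seed = 23))
  cand <- truth
  substr(cand, 400, 400) <- setdiff(c("A", "C", "G", "T"),
                                    substr(truth, 400, 400))[1]
  polished <- consensus_polish(cand, reads)
  expect_equal(polished, truth)
})

test_that("the QUBO route beats or ties the prescriptive baseline", {
  # end-to-end regression: on noiseless instances the optimizer should
  # report at most as many contigs as zero-copy decomposition, at high
  # identity; with a skipped node it bridges the gap the baseline cannot
  wins <- 0; idents <- numeric(0)
  for (seed in 1:8) {
    skip <- if (seed %% 2 == 0) 3L else integer(0)
    node_len <- rep(400, 6)
    if (length(skip)) node_len[skip] <- 60
    ins <- make_instance("line", n_nodes = 6, node_length = node_len,
                         skip_nodes = skip, seed = seed + 300)
    out <- assemble_evaluate(ins$graph, ins$truth_sequence,
                             variant = "oriented", seed = seed)
    base_contigs <- length(prescriptive_decompose(ins$graph))
    if (out$report$n_contigs <= base_contigs) wins <- wins + 1
    idents <- c(idents, out$report$identity_pct)
  }
  expect_gte(wins, 6)
  expect_true(all(idents >= 95))
})
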