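test_that("configuration invariants are enforced", {
  expect_error(evolution_config(point_rate = -1), "rates")
  expect_error(evolution_config(descendant_rate_factor = 0), "factor")
  expect_error(evolution_config(population_size = 0), "population_size")
  expect_error(read_config(coverage = 0), "coverage")
  expect_error(read_config(sub_error_rate = 1), "sub_error_rate")
})

test_that("zero mutation rates give an identical population", {
  cfg <- evolution_config(initial_length = 500, population_size = 5,
                          generations = 2, str_rate = 0, cnv_rate = 0,
                          short_repeat_rate = 0, long_repeat_rate = 0,
                          translocation_rate = 0, inversion_rate = 0,
                          point_rate = 0, seed = 3)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 5)
  expect_length(unique(pop$genome), 1)
  expect_true(is.na(pop$parent[1]))
  expect_true(all(pop$parent[-1] >= 1))
})

test_that("the default configuration yields 100 genomes over 10 generations", {
  cfg <- evolution_config(initial_length = 400, seed = 5)
  expect_equal(cfg$population_size, 100)
  expect_equal(cfg$generations, 10)
  pop <- generate_population(evolution_config(
    initial_length = 1000, population_size = 20, generations = 4, seed = 5))
  expect_equal(nrow(pop), 20)
  # parents always predate their children
  expect_true(all(pop$parent[-1] < seq_len(19) + 1))
})

test_that("population generation is reproducible and seed-sensitive", {
  cfg <- evolution_config(initial_length = 800, population_size = 6,
                          generations = 2, seed = 7)
  expect_identical(generate_population(cfg), generate_population(cfg))
  cfg2 <- cfg; cfg2$seed <- 8
  expect_false(identical(generate_population(cfg), generate_population(cfg2)))
})

test_that("point mutations hit at the binomial rate", {
  r <- 0.01; f <- 0.5; L <- 2000
  cfg <- evolution_config(initial_length = L, population_size = 51,
                          generations = 1, str_rate = 0, cnv_rate = 0,
                          short_repeat_rate = 0, long_repeat_rate = 0,
                          translocation_rate = 0, inversion_rate = 0,
                          point_rate = r, descendant_rate_factor = f,
                          seed = 13)
  pop <- generate_population(cfg)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  d <- vapply(2:51, function(i) {
    # compare against the recorded parent (lengths never change here)
    hamming(pop$genome[i], pop$genome[pop$parent[i]])
  }, numeric(1))
  # children of mutated parents still differ by ~Binom(L, r*f) from them
  expect_lt(abs(mean(d) - L * r * f), 3 * sqrt(L * r * f * (1 - r * f) / 50))
})

test_that("inversion-only mutation preserves genome length exactly", {
  cfg <- evolution_config(initial_length = 3000, population_size = 8,
                          generations = 2, str_rate = 0, cnv_rate = 0,
                          short_repeat_rate = 0, long_repeat_rate = 0,
                          translocation_rate = 0, inversion_rate = 5e-3,
                          point_rate = 0, descendant_rate_factor = 1,
                          seed = 21)
  pop <- generate_population(cfg)
  expect_true(all(nchar(pop$genome) == nchar(pop$genome[1])))
  expect_gt(length(unique(pop$genome)), 1)  # inversions did happen
})

test_that("too-short founders are rejected", {
  expect_error(generate_population(evolution_config(initial_length = 100)),
               "longest repeat")
})

test_that("shred_reads follows the coverage arithmetic", {
  set.seed(1)
  genome <- random_dna(10000)
  rc <- read_config(coverage = 30, read_length = 100, sub_error_rate = 0,
                    seed = 2)
  reads <- shred_reads(genome, rc)
  expect_length(reads, 3000)
  expect_true(all(nchar(reads) == 100))
  expect_error(shred_reads(random_dna(50), rc), "read_length")
  # total sequenced bases match coverage within one read length of exact
  expect_lt(abs(sum(nchar(reads)) / nchar(genome) - 30), 100 / 10000 + 1e-9)
})

test_that("error-free reads are exact substrings of genome or its revcomp", {
  set.seed(4)
  genome <- random_dna(2000)
  reads <- shred_reads(genome, read_config(5, 80, 0, seed = 5))
  both <- c(genome, revcomp(genome))
  for (rd in reads[1:50])
    expect_true(any(vapply(both, grepl, logical(1), pattern = rd,
                           fixed = TRUE)))
})

test_that("substitution errors appear at the configured binomial rate", {
  set.seed(6)
  genome <- random_dna(5000)
  rc <- read_config(coverage = 20, read_length = 100, sub_error_rate = 0.01,
                    seed = 7)
  reads <- shred_reads(genome, rc)[1:1000]
  clean <- shred_reads(genome, read_config(20, 100, 0, seed = 7))[1:1000]
  mism <- vapply(seq_along(reads), function(i) {
    sum(strsplit(reads[i], "")[[1]] != strsplit(clean[i], "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(mism) - 1.0), 3 * sqrt(100 * 0.01 * 0.99 / 1000))
})

test_that("shredding is reproducible per seed", {
  set.seed(8); genome <- random_dna(1000)
  rc <- read_config(10, 50, 0.01, seed = 9)
  expect_identical(shred_reads(genome, rc), shred_reads(genome, rc))
})

test_that("make_instance reproduces the (1,1,0,1,1) zero-copy situation", {
  ins <- make_instance("line", n_nodes = 5, node_length = 50,
                       skip_nodes = 3, seed = 2)
  expect_equal(ins$graph$nodes$weight, c(1, 1, 0, 1, 1))
  expect_length(ins$truth_walks, 2)
  expect_equal(ins$truth_walks[[1]]$node, c("n01", "n02"))
  expect_equal(ins$truth_walks[[2]]$node, c("n04", "n05"))
  # truth sequence is the genome with the skipped node deleted
  expect_equal(nchar(ins$truth_sequence), 4 * 50)
  for (w in ins$truth_walks)
    expect_length(validate_walk(ins$graph, w), 0)
})

test_that("noiseless weights equal truth-walk visit counts", {
  for (shape in c("line", "cycle", "tangle", "random")) {
    ins <- make_instance(shape, n_nodes = 6, node_length = 40,
                         walk_length = 8, seed = 17)
    visits <- setNames(numeric(6), ins$graph$nodes$id)
    for (w in ins$truth_walks) {
      tab <- table(w$node)
      visits[names(tab)] <- visits[names(tab)] + tab
    }
    expect_equal(ins$graph$nodes$weight, unname(visits), label = shape)
    for (w in ins$truth_walks)
      expect_length(validate_walk(ins$graph, w), 0)
  }
})

test_that("a tangle instance revisits nodes, giving weight 2", {
  ins <- make_instance("tangle", n_nodes = 6, node_length = 40, seed = 3)
  expect_true(any(ins$graph$nodes$weight >= 2))
})

test_that("weight noise is truncated at zero and rounded to one decimal", {
  ins <- make_instance("line", n_nodes = 8, node_length = 30,
                       weight_noise_sd = 0.6, seed = 5)
  w <- ins$graph$nodes$weight
  expect_true(all(w >= 0))
  expect_equal(w, round(w, 1))
  expect_match(ins$noise_model, "gaussian")
})

test_that("diploid instances carry a walk per haplotype", {
  ins <- make_instance("line", n_nodes = 4, node_length = 30,
                       orientation = "diploid", seed = 6)
  expect_equal(sort(unique(ins$hap)), c(1, 2))
  expect_length(ins$truth_sequence, 2)
  expect_equal(ins$graph$nodes$weight, rep(2, 4))  # both haps walk the line
})

test_that("instances are bitwise reproducible per seed", {
  a <- make_instance("random", n_nodes = 5, walk_length = 6, seed = 12)
  b <- make_instance("random", n_nodes = 5, walk_length = 6, seed = 12)
  expect_identical(a$graph$nodes, b$graph$nodes)
  expect_identical(a$truth_sequence, b$truth_sequence)
})
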