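# Synthetic genome populations, shotgun reads, and annotated graph
# instances with known ground truth. The generator emulates the
# problem-creation stage of the pipeline: a founder genome accumulates
# structural and point mutations, descendants mutate at a reduced rate, a
# target genome is shredded to short reads, and graph instances carry a
# truth walk whose visit counts define the noiseless node weights.

#' Configuration for the genome-population simulator
#'
#' Rates are per base of the genome: structural classes draw a Poisson
#' number of events with mean `rate * length`, point mutations substitute
#' each base independently with probability `rate`. Descendants use every
#' rate multiplied by `descendant_rate_factor`.
#'
#' @param initial_length founder genome length in bases (default 10000).
#' @param population_size number of genomes (default 100).
#' @param generations number of descent rounds over which the population
#'   is grown (default 10).
#' @param str_rate short-tandem-repeat expansion events per base
#'   (2-6 bp unit duplicated in place; default 3e-4).
#' @param cnv_rate copy-number events per base (100-1000 bp segment
#'   duplicated in tandem; default 1e-4).
#' @param short_repeat_rate insertions per base of a 50 bp element from a
#'   fixed library (default 2e-4).
#' @param long_repeat_rate insertions per base of a 500 bp library element
#'   (default 5e-5).
#' @param translocation_rate cut-and-paste events per base (100-1000 bp
#'   segment; default 5e-5).
#' @param inversion_rate in-place reverse-complement events per base
#'   (100-1000 bp segment; default 5e-5).
#' @param point_rate per-base substitution probability (default 0.002).
#' @param descendant_rate_factor multiplier in (0, 1] applied to all rates
#'   for descendants (default 0.1).
#' @param seed RNG seed (default 1).
#' @return object of class `evolution_config`.
#' @export
evolution_config <- function(initial_length = 10000, population_size = 100,
                             generations = 10,
                             str_rate = 3e-4, cnv_rate = 1e-4,
                             short_repeat_rate = 2e-4,
                             long_repeat_rate = 5e-5,
                             translocation_rate = 5e-5,
                             inversion_rate = 5e-5, point_rate = 0.002,
                             descendant_rate_factor = 0.1, seed = 1) {
  cfg <- list(initial_length = initial_length,
              population_size = population_size, generations = generations,
              str_rate = str_rate, cnv_rate = cnv_rate,
              short_repeat_rate = short_repeat_rate,
              long_repeat_rate = long_repeat_rate,
              translocation_rate = translocation_rate,
              inversion_rate = inversion_rate, point_rate = point_rate,
              descendant_rate_factor = descendant_rate_factor, seed = seed)
  rates <- unlist(cfg[grep("_rate$", names(cfg))])
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (descendant_rate_factor <= 0 || descendant_rate_factor > 1)
    stop("descendant_rate_factor must be in (0, 1]")
  if (population_size < 1) stop("population_size must be >= 1")
  structure(cfg, class = "evolution_config")
}

#' Configuration for the shotgun-read simulator
#'
#' @param coverage fold coverage (default 30, the pipeline's standard
#'   sequencing depth).
#' @param read_length read length in bases (default 150).
#' @param sub_error_rate per-base substitution-error probability
#'   (default 0.005); indel errors are not modelled.
#' @param seed RNG seed (default 1).
#' @return object of class `read_config`.
#' @export
read_config <- function(coverage = 30, read_length = 150,
                        sub_error_rate = 0.005, seed = 1) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (sub_error_rate < 0 || sub_error_rate >= 1)
    stop("sub_error_rate must be in [0, 1)")
  structure(list(coverage = coverage, read_length = read_length,
                 sub_error_rate = sub_error_rate, seed = seed),
            class = "read_config")
}

# --- mutation operators (character-vector genomes) --------------------------

point_mutate <- function(bases, rate) {
  if (rate <= 0) return(bases)
  hit <- which(runif(length(bases)) < rate)
  if (length(hit)) {
    for (i in hit) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  bases
}

insert_at <- function(bases, pos, piece) {
  # insert piece after position pos (0 = front)
  append(bases, piece, after = pos)
}

random_span <- function(L, lo, hi) {
  len <- sample(lo:min(hi, L), 1)
  start <- sample(seq_len(L - len + 1), 1)
  c(start, start + len - 1)
}

str_expand <- function(bases) {
  L <- length(bases)
  if (L < 6) return(bases)
  unit_len <- sample(2:6, 1)
  start <- sample(seq_len(L - unit_len + 1), 1)
  unit <- bases[start:(start + unit_len - 1)]
  copies <- sample(1:10, 1)
  insert_at(bases, start + unit_len - 1, rep(unit, copies))
}

cnv_duplicate <- function(bases) {
  L <- length(bases)
  if (L < 100) return(bases)
  sp <- random_span(L, 100, 1000)
  insert_at(bases, sp[2], bases[sp[1]:sp[2]])
}

repeat_insert <- function(bases, element) {
  pos <- sample(0:length(bases), 1)
  insert_at(bases, pos, element)
}

translocate <- function(bases) {
  L <- length(bases)
  if (L < 200) return(bases)
  sp <- random_span(L, 100, 1000)
  piece <- bases[sp[1]:sp[2]]
  rest <- bases[-(sp[1]:sp[2])]
  pos <- sample(0:length(rest), 1)
  insert_at(rest, pos, piece)
}

invert_segment <- function(bases) {
  L <- length(bases)
  if (L < 100) return(bases)
  sp <- random_span(L, 100, 1000)
  seg <- paste(bases[sp[1]:sp[2]], collapse = "")
  bases[sp[1]:sp[2]] <- strsplit(revcomp(seg), "")[[1]]
  bases
}

mutate_genome <- function(bases, cfg, factor, library) {
  L <- length(bases)
  n_ev <- function(rate) rpois(1, rate * factor * L)
  for (i in seq_len(n_ev(cfg$str_rate))) bases <- str_expand(bases)
  for (i in seq_len(n_ev(cfg$cnv_rate))) bases <- cnv_duplicate(bases)
  for (i in seq_len(n_ev(cfg$short_repeat_rate)))
    bases <- repeat_insert(bases, library$short[[sample(length(library$short), 1)]])
  for (i in seq_len(n_ev(cfg$long_repeat_rate)))
    bases <- repeat_insert(bases, library$long[[sample(length(library$long), 1)]])
  for (i in seq_len(n_ev(cfg$translocation_rate))) bases <- translocate(bases)
  for (i in seq_len(n_ev(cfg$inversion_rate))) bases <- invert_segment(bases)
  point_mutate(bases, cfg$point_rate * factor)
}

#' Generate a related genome population
#'
#' Genome 1 (the founder) is a random base string passed once through the
#' mutation processes at the founder rates; every later genome is derived
#' from a single randomly chosen earlier genome, mutated at the
#' descendant rates (`rate * descendant_rate_factor`). The population is
#' grown over `generations` rounds of roughly equal size, each round
#' drawing parents from all genomes created so far. Identical seeds give
#' identical output.
#'
#' @param config an `evolution_config`.
#' @return data frame with columns `genome` (DNA string) and `parent`
#'   (index of the parent genome; NA for the founder).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  lib_max <- 0
  if (config$long_repeat_rate > 0) lib_max <- 500
  else if (config$short_repeat_rate > 0) lib_max <- 50
  else if (config$str_rate > 0) lib_max <- 6
  if (config$initial_length < lib_max)
    stop("initial_length (", config$initial_length,
         ") is shorter than the longest repeat/STR unit (", lib_max, ")")
  local_seed(config$seed, {
    library <- list(
      short = replicate(5, strsplit(random_dna(50), "")[[1]], simplify = FALSE),
      long = replicate(3, strsplit(random_dna(500), "")[[1]], simplify = FALSE)
    )
    founder <- strsplit(random_dna(config$initial_length), "")[[1]]
    founder <- mutate_genome(founder, config, 1, library)
    genomes <- list(founder)
    parents <- NA_integer_
    n_left <- config$population_size - 1
    per_gen <- rep(n_left %/% config$generations, config$generations)
    if (n_left %% config$generations > 0)
      per_gen[seq_len(n_left %% config$generations)] <-
        per_gen[seq_len(n_left %% config$generations)] + 1
    for (g in seq_len(config$generations)) {
      for (i in seq_len(per_gen[g])) {
        parent <- sample(length(genomes), 1)
        child <- mutate_genome(genomes[[parent]], config,
                               config$descendant_rate_factor, library)
        genomes[[length(genomes) + 1L]] <- child
        parents <- c(parents, parent)
      }
    }
    data.frame(
      genome = vapply(genomes, paste, character(1), collapse = ""),
      parent = parents, stringsAsFactors = FALSE
    )
  })
}

#' Simulate single-end shotgun reads
#'
#' Draws `round(coverage * L / read_length)` reads with uniformly random
#' start positions and strands, then applies i.i.d. base-substitution
#' errors (each error picks a uniformly random different base). No indel
#' errors are modelled. Deterministic for a fixed seed.
#'
#' @param genome DNA string.
#' @param config a `read_config`.
#' @return named character vector of read sequences (`read_1`, ...).
#' @export
shred_reads <- function(genome, config) {
  stopifnot(inherits(config, "read_config"))
  L <- nchar(genome)
  R <- config$read_length
  if (R > L) stop("read_length (", R, ") exceeds genome length (", L, ")")
  n_reads <- round(config$coverage * L / R)
  local_seed(config$seed, {
    starts <- sample.int(L - R + 1, n_reads, replace = TRUE)
    fwd <- substring(genome, starts, starts + R - 1)
    flip <- runif(n_reads) < 0.5
    reads <- fwd
    if (any(flip)) reads[flip] <- revcomp(fwd[flip])
    if (config$sub_error_rate > 0) {
      n_err <- rbinom(n_reads, R, config$sub_error_rate)
      for (i in which(n_err > 0)) {
        b <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(R, n_err[i])
        for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
        reads[i] <- paste(b, collapse = "")
      }
    }
    setNames(reads, paste0("read_", seq_len(n_reads)))
  })
}

# --- graph instances with known truth ---------------------------------------

instance_edges <- function(shape, n, seed_offset_rng_active = TRUE) {
  ids <- paste0("n", sprintf("%02d", seq_len(n)))
  e <- function(i, j) data.frame(from = ids[i], from_orient = "+",
                                 to = ids[j], to_orient = "+",
                                 stringsAsFactors = FALSE)
  edges <- empty_edges()
  if (n > 1)
    edges <- do.call(rbind, lapply(seq_len(n - 1), function(i) e(i, i + 1)))
  if (shape == "cycle" && n > 1) edges <- rbind(edges, e(n, 1))
  list(ids = ids, edges = edges)
}

#' Generate a synthetic annotated-graph instance with known truth
#'
#' Builds a graph of the requested shape, samples a ground-truth walk,
#' sets each node's weight to its total visit count (optionally with
#' truncated-at-zero Gaussian noise, rounded to one decimal), and returns
#' graph, truth walk(s) and truth sequence together.
#'
#' Shapes: `"line"` (simple path, truth walks it once), `"cycle"` (truth
#' goes around until `walk_length` steps), `"tangle"` (a line with a back
#' edge so a stretch of nodes is traversed twice), `"random"` (random
#' edges, random walk of `walk_length` steps). `skip_nodes` marks nodes
#' absent from the target genome: their weight is 0 and the truth walk is
#' split around them into valid sub-walks (the classic zero-copy
#' situation the cost-function approach is designed to bridge).
#'
#' @param shape `"line"`, `"cycle"`, `"tangle"` or `"random"`.
#' @param n_nodes number of nodes (>= 1).
#' @param node_length node sequence length in bases (scalar or vector,
#'   default 300).
#' @param walk_length walk length for `"cycle"`/`"random"` shapes
#'   (default `n_nodes`).
#' @param weight_noise_sd sd of the Gaussian weight perturbation
#'   (default 0: weights equal visit counts exactly).
#' @param orientation `"plain"`, `"oriented"` or `"diploid"`.
#' @param skip_nodes integer indices of nodes dropped from the truth
#'   walk (their true copy number is 0).
#' @param seed RNG seed.
#' @return object of class `synthetic_instance`: `graph`, `truth_walks`
#'   (list of valid `walk`s; one per haplotype contig), `truth_sequence`
#'   (one string per haplotype), `noise_model`, `variant`.
#' @export
make_instance <- function(shape = "line", n_nodes = 5, node_length = 300,
                          walk_length = n_nodes, weight_noise_sd = 0,
                          orientation = "oriented",
                          skip_nodes = integer(0), seed = 1) {
  stopifnot(shape %in% c("line", "cycle", "tangle", "random"))
  check_variant(orientation)
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  if (walk_length < 0) stop("walk_length must be >= 0")
  local_seed(seed, {
    node_length <- rep_len(node_length, n_nodes)
    sk <- instance_edges(if (shape == "cycle") "cycle" else "line", n_nodes)
    ids <- sk$ids; edges <- sk$edges
    if (shape == "tangle" && n_nodes >= 3) {
      # the repeated stretch spans at most a third of the nodes, so
      # single-copy sequence dominates (as in real pangenome tangles)
      r <- sample(seq_len(max(1, ceiling(n_nodes / 3))), 1)
      i <- sample(seq_len(n_nodes - r), 1)
      j <- i + r - 1  # j <= n_nodes - 1 by construction
      edges <- rbind(edges, data.frame(
        from = ids[j], from_orient = "+", to = ids[i], to_orient = "+",
        stringsAsFactors = FALSE))
    }
    if (shape == "random") {
      extra <- max(n_nodes, 2)
      for (k in seq_len(extra)) {
        ij <- sample(n_nodes, 2, replace = TRUE)
        edges <- rbind(edges, data.frame(
          from = ids[ij[1]], from_orient = "+", to = ids[ij[2]],
          to_orient = "+", stringsAsFactors = FALSE))
      }
      edges <- unique(edges)
    }
    if (walk_length > 0 && nrow(edges) == 0 && n_nodes > 1)
      stop("walk_length > 0 but the graph has no edges")

    # truth walk(s) over node indices
    sample_walk <- function() {
      if (shape == "line") return(seq_len(n_nodes))
      if (shape == "cycle")
        return(((seq_len(max(walk_length, 1)) - 1) %% n_nodes) + 1)
      if (shape == "tangle" && n_nodes >= 3) {
        back <- edges[nrow(edges), ]
        j <- match(back$from, ids); i <- match(back$to, ids)
        return(c(seq_len(j), i:n_nodes))
      }
      # random: follow out-edges, stop when stuck
      out <- lapply(seq_len(n_nodes), function(i)
        match(edges$to[edges$from == ids[i]], ids))
      cur <- sample(n_nodes, 1)
      path <- cur
      while (length(path) < walk_length) {
        nxt <- out[[cur]]
        if (length(nxt) == 0) break
        cur <- nxt[sample(length(nxt), 1)]
        path <- c(path, cur)
      }
      path
    }
    walks_idx <- if (orientation == "diploid") list(sample_walk(), sample_walk())
                 else list(sample_walk())

    # drop skipped nodes: weight 0, truth walk split into valid sub-walks
    split_skips <- function(idx) {
      keep <- !(idx %in% skip_nodes)
      if (all(keep)) return(list(idx))
      runs <- split(idx[keep], cumsum(!keep)[keep])
      Filter(length, unname(runs))
    }
    truth_parts <- lapply(walks_idx, split_skips)

    visits <- tabulate(unlist(lapply(truth_parts, unlist)), nbins = n_nodes)
    weights <- as.numeric(visits)
    noise_model <- "none"
    if (weight_noise_sd > 0) {
      weights <- round(pmax(0, weights + rnorm(n_nodes, 0, weight_noise_sd)), 1)
      noise_model <- sprintf("gaussian(sd=%g), truncated at 0, 1dp", weight_noise_sd)
    }
    seqs <- vapply(node_length, random_dna, character(1))
    graph <- annotated_graph(
      data.frame(id = ids, seq = seqs, weight = weights,
                 stringsAsFactors = FALSE),
      edges
    )
    truth_walks <- lapply(unlist(truth_parts, recursive = FALSE),
                          function(idx) walk(ids[idx], "+"))
    hap_of_walk <- rep(seq_along(truth_parts), lengths(truth_parts))
    truth_sequence <- vapply(seq_along(truth_parts), function(h) {
      paste(vapply(truth_parts[[h]], function(idx)
        paste(seqs[idx], collapse = ""), character(1)), collapse = "")
    }, character(1))
    structure(list(
      graph = graph, truth_walks = truth_walks, hap = hap_of_walk,
      truth_sequence = truth_sequence, noise_model = noise_model,
      variant = orientation, seed = seed
    ), class = "synthetic_instance")
  })
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "synthetic_instance: %s, %d nodes, %d truth walk(s), noise: %s\n",
    x$variant, nrow(x$graph$nodes), length(x$truth_walks), x$noise_model))
  invisible(x)
}
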