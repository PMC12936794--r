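# Fixtures built in code: small graphs and random instances shared across
# test files.

# The five-node line graph A->B->C->D->E with copy numbers (1,1,0,1,1):
# the canonical zero-copy situation a prescriptive decomposition splits
# and the cost-function approach bridges.
line_graph_11011 <- function(node_length = 20, seed = 101) {
  set.seed(seed)
  annotated_graph(
    data.frame(id = LETTERS[1:5],
               seq = vapply(rep(node_length, 5), random_dna, character(1)),
               weight = c(1, 1, 0, 1, 1)),
    data.frame(from = LETTERS[1:4], from_orient = "+",
               to = LETTERS[2:5], to_orient = "+")
  )
}

# Random small weighted graph for property tests: n nodes, random "+/+"
# edges (plus closure), integer weights in 0..wmax.
random_small_graph <- function(n_nodes, seed, edge_prob = 0.5, wmax = 2) {
  set.seed(seed)
  ids <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pick <- runif(nrow(pairs)) < edge_prob
  edges <- pairs[pick, , drop = FALSE]
  edges$from_orient <- rep("+", nrow(edges))
  edges$to_orient <- rep("+", nrow(edges))
  annotated_graph(
    data.frame(id = ids,
               seq = vapply(rep(12, n_nodes), random_dna, character(1)),
               weight = sample(0:wmax, n_nodes, replace = TRUE)),
    edges[, c("from", "from_orient", "to", "to_orient")]
  )
}

# A random valid walk of exactly len steps over "+" sites (NULL if the
# graph cannot support one from the sampled start).
random_plain_walk <- function(graph, len, seed) {
  set.seed(seed)
  if (len == 0) return(walk())
  ids <- graph$nodes$id
  out_of <- function(v) {
    e <- graph$edges
    e$to[e$from == v & e$from_orient == "+" & e$to_orient == "+"]
  }
  for (attempt in 1:20) {
    cur <- sample(ids, 1)
    path <- cur
    ok <- TRUE
    while (length(path) < len) {
      nxt <- out_of(cur)
      if (length(nxt) == 0) { ok <- FALSE; break }
      cur <- nxt[sample.int(length(nxt), 1)]
      path <- c(path, cur)
    }
    if (ok) return(walk(path, "+"))
  }
  NULL
}

# GFA text written to a temp file, returned as the path.
write_gfa_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gfa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
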