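# Oriented, vertex-weighted pangenome graph model and GFA 1.0 I/O.
#
# Nodes carry a DNA sequence, a real copy-number estimate (`weight`; -1 is
# the in-memory sentinel for "unknown") and a raw k-mer hit count. Edges are
# oriented links closed under reverse-complement pairing: (A,oA)->(B,oB)
# present iff (B,flip(oB))->(A,flip(oA)) present. An unoriented (plain)
# problem is represented by the same structure with walks restricted to "+".

flip_orient <- function(o) ifelse(o == "+", "-", "+")

edge_key <- function(from, from_orient, to, to_orient) {
  paste(from, from_orient, to, to_orient, sep = "\r")
}

mirror_edges <- function(edges) {
  data.frame(
    from = edges$to, from_orient = flip_orient(edges$to_orient),
    to = edges$from, to_orient = flip_orient(edges$from_orient),
    stringsAsFactors = FALSE
  )
}

empty_edges <- function() {
  data.frame(from = character(0), from_orient = character(0),
             to = character(0), to_orient = character(0),
             stringsAsFactors = FALSE)
}

#' Construct an annotated pangenome graph
#'
#' @param nodes data frame with columns `id`, `seq`, and optionally
#'   `weight` (copy-number estimate, default 0; -1 marks unknown) and
#'   `raw_count` (k-mer hits, default 0).
#' @param edges data frame with columns `from`, `from_orient`, `to`,
#'   `to_orient` (orientations `"+"`/`"-"`); may be missing implied
#'   reverse-complement mirrors, which are added.
#' @param complete_closure add implied reverse-complement edges (default
#'   TRUE).
#' @return an object of class `annotated_graph`.
#' @export
annotated_graph <- function(nodes, edges = empty_edges(),
                            complete_closure = TRUE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "seq") %in% names(nodes)))
    stop("nodes must have columns 'id' and 'seq'")
  nodes$id <- as.character(nodes$id)
  nodes$seq <- toupper(as.character(nodes$seq))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  if (length(nodes$seq) && any(grepl("[^ACGTN]", nodes$seq)))
    stop("node sequences must be over {A,C,G,T,N}")
  if (is.null(nodes$weight)) nodes$weight <- 0
  if (is.null(nodes$raw_count)) nodes$raw_count <- 0L
  nodes$length <- nchar(nodes$seq)
  nodes <- nodes[, c("id", "seq", "length", "weight", "raw_count")]
  if (any(nodes$weight < 0 & nodes$weight != -1))
    stop("weights must be >= 0 (or the -1 'unknown' sentinel)")

  for (col in c("from", "to")) edges[[col]] <- as.character(edges[[col]])
  if (nrow(edges)) {
    if (!all(edges$from_orient %in% c("+", "-")) ||
        !all(edges$to_orient %in% c("+", "-")))
      stop("edge orientations must be '+' or '-'")
    bad <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(bad)) stop("edge references unknown node: ", bad[1])
  }
  if (complete_closure && nrow(edges)) {
    all_e <- rbind(edges, mirror_edges(edges))
    keys <- edge_key(all_e$from, all_e$from_orient, all_e$to, all_e$to_orient)
    edges <- all_e[!duplicated(keys), , drop = FALSE]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, oriented = TRUE),
            class = "annotated_graph")
}

#' @export
print.annotated_graph <- function(x, ...) {
  cat(sprintf("annotated_graph: %d nodes, %d oriented edges, %d bp\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$length)))
  invisible(x)
}

graph_edge_keys <- function(graph) {
  with(graph$edges, edge_key(from, from_orient, to, to_orient))
}

#' Construct a walk (ordered oriented node visits)
#'
#' @param node character vector of node ids.
#' @param orient character vector of orientations (`"+"`/`"-"`), recycled;
#'   default all `"+"`.
#' @return an object of class `walk` (a data frame with columns `node`,
#'   `orient`); may be empty.
#' @export
walk <- function(node = character(0), orient = "+") {
  node <- as.character(node)
  orient <- rep_len(as.character(orient), length(node))
  if (length(orient) && !all(orient %in% c("+", "-")))
    stop("orientations must be '+' or '-'")
  structure(data.frame(node = node, orient = orient,
                       stringsAsFactors = FALSE),
            class = c("walk", "data.frame"))
}

#' Pair of walks (diploid solution object)
#'
#' @param first,second `walk` objects.
#' @return object of class `walk_pair`.
#' @export
walk_pair <- function(first, second) {
  stopifnot(inherits(first, "walk"), inherits(second, "walk"))
  structure(list(first = first, second = second), class = "walk_pair")
}

#' Check a walk against the graph's edge set
#'
#' A walk is valid when every consecutive pair of steps traverses an
#' oriented edge of the graph.
#'
#' @param graph an `annotated_graph`.
#' @param walk a `walk`.
#' @return integer vector of 0-based indices of steps whose transition
#'   into the next step is not an edge; empty when the walk is valid.
#' @export
validate_walk <- function(graph, walk) {
  stopifnot(inherits(graph, "annotated_graph"), inherits(walk, "walk"))
  unknown <- setdiff(walk$node, graph$nodes$id)
  if (length(unknown)) stop("walk references unknown node: ", unknown[1])
  n <- nrow(walk)
  if (n < 2) return(integer(0))
  keys <- edge_key(walk$node[-n], walk$orient[-n],
                   walk$node[-1], walk$orient[-1])
  which(!(keys %in% graph_edge_keys(graph))) - 1L
}

# ---- GFA 1.0 ---------------------------------------------------------------

parse_gfa_tags <- function(fields, lineno) {
  tags <- list()
  for (f in fields) {
    m <- regmatches(f, regexec("^([A-Za-z][A-Za-z0-9]):([ABHJZif]):(.*)$", f))[[1]]
    if (length(m) != 4)
      stop("malformed tag on line ", lineno, ": '", f, "'")
    val <- switch(m[3], i = as.integer(m[4]), f = as.numeric(m[4]), m[4])
    tags[[m[2]]] <- val
  }
  tags
}

#' Read a GFA 1.0 pangenome graph
#'
#' Supports S (segment) and L (link) lines. Raw k-mer counts are read from
#' the `KC:i` tag and copy-number estimates from the `CN:f` tag; missing
#' tags default to 0. Link overlaps other than `0M` or `*` are rejected.
#' Edge closure (implied reverse-complement links) is completed
#' automatically, with a warning when completion added edges.
#'
#' @param path path to a GFA 1.0 file.
#' @return an `annotated_graph`.
#' @export
parse_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); seqs <- character(0)
  weights <- numeric(0); raws <- integer(0)
  ef <- character(0); efo <- character(0); et <- character(0); eto <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rec <- fields[1]
    if (rec == "H") next
    if (rec == "S") {
      if (length(fields) < 3)
        stop("malformed S line at line ", i)
      id <- fields[2]
      if (id %in% ids) stop("duplicate node id '", id, "' at line ", i)
      sq <- toupper(fields[3])
      if (sq == "*") stop("S line without sequence at line ", i)
      if (grepl("[^ACGTN]", sq))
        stop("non-ACGTN sequence at line ", i)
      tags <- parse_gfa_tags(fields[-(1:3)], i)
      ids <- c(ids, id); seqs <- c(seqs, sq)
      weights <- c(weights, if (!is.null(tags$CN)) tags$CN else 0)
      raws <- c(raws, if (!is.null(tags$KC)) as.integer(tags$KC) else 0L)
    } else if (rec == "L") {
      if (length(fields) < 6)
        stop("malformed L line at line ", i)
      if (!fields[6] %in% c("0M", "*"))
        stop("unsupported link overlap '", fields[6], "' at line ", i,
             " (only 0M or * are accepted)")
      if (!fields[3] %in% c("+", "-") || !fields[5] %in% c("+", "-"))
        stop("malformed orientation at line ", i)
      ef <- c(ef, fields[2]); efo <- c(efo, fields[3])
      et <- c(et, fields[4]); eto <- c(eto, fields[5])
    } else {
      stop("unsupported GFA record type '", rec, "' at line ", i,
           " (only H, S and L lines are handled)")
    }
  }
  bad <- setdiff(c(ef, et), ids)
  if (length(bad)) stop("link references unknown node: ", bad[1])
  edges <- data.frame(from = ef, from_orient = efo, to = et, to_orient = eto,
                      stringsAsFactors = FALSE)
  n_in <- nrow(unique(edges))
  g <- annotated_graph(
    data.frame(id = ids, seq = seqs, weight = weights, raw_count = raws,
               stringsAsFactors = FALSE),
    edges
  )
  if (nrow(g$edges) > n_in)
    warning("edge closure completed: added ", nrow(g$edges) - n_in,
            " implied reverse-complement link(s)")
  g
}

format_cn <- function(w) {
  # full-precision float tag so fractional estimates round-trip losslessly
  sub("0+$", "", sub("\\.?0+$", "", sprintf("%.12f", w)))
}

#' Write a graph to GFA 1.0
#'
#' Raw counts are written as `KC:i` and copy-number estimates as `CN:f`;
#' nodes whose weight is the -1 "unknown" sentinel get no `CN` tag. All
#' oriented edges (including closure mirrors) are written, so
#' `parse_gfa(write_gfa(g))` reproduces `g` up to row order.
#'
#' @param graph an `annotated_graph`.
#' @param path output file path.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "annotated_graph"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  nd <- graph$nodes
  for (i in seq_len(nrow(nd))) {
    tags <- sprintf("LN:i:%d\tKC:i:%d", nd$length[i], nd$raw_count[i])
    if (nd$weight[i] >= 0)
      tags <- paste0(tags, "\tCN:f:", format(nd$weight[i], digits = 15,
                                             scientific = FALSE))
    writeLines(sprintf("S\t%s\t%s\t%s", nd$id[i], nd$seq[i], tags), con)
  }
  ed <- graph$edges
  if (nrow(ed))
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t0M", ed$from, ed$from_orient,
                       ed$to, ed$to_orient), con)
  invisible(path)
}

#' Compare two graphs up to node/edge ordering
#'
#' @param a,b `annotated_graph` objects.
#' @param tol numeric tolerance on weights.
#' @return TRUE or FALSE.
#' @export
graphs_equal <- function(a, b, tol = 1e-9) {
  na <- a$nodes[order(a$nodes$id), ]; nb <- b$nodes[order(b$nodes$id), ]
  if (nrow(na) != nrow(nb)) return(FALSE)
  if (!identical(na$id, nb$id) || !identical(na$seq, nb$seq)) return(FALSE)
  if (!identical(na$raw_count, nb$raw_count)) return(FALSE)
  if (any(abs(na$weight - nb$weight) > tol)) return(FALSE)
  setequal(graph_edge_keys(a), graph_edge_keys(b))
}

#' Basic size statistics of a graph
#'
#' @param graph an `annotated_graph`.
#' @return named list: node count, edge count, total bases, weighted nodes.
#' @export
graph_stats <- function(graph) {
  list(
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    total_bases = sum(graph$nodes$length),
    n_weighted = sum(graph$nodes$weight > 0)
  )
}
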