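# Copy-number annotation from short reads: index each node's canonical
# k-mers, count read k-mers that hit exactly one node (k-mers shared by
# several nodes are dropped, the analogue of filtering secondary
# alignments), and depth-normalize the counts into per-node copy-number
# estimates. K-mers containing N are excluded throughout.

#' Index the k-mers of every graph node
#'
#' For each node of length >= k, records the multiset of canonical k-mers
#' (lexicographic minimum of the k-mer and its reverse complement), the
#' set of nodes owning each k-mer, and each node's unique fraction: the
#' share of its k-mer positions whose canonical k-mer occurs in no other
#' node. The unique fraction is the k-mer hit-rate expectation used to
#' normalize observed counts.
#'
#' @param graph an `annotated_graph`.
#' @param k k-mer size (>= 3; default 31).
#' @return object of class `kmer_index`: `k`, `node_kmers` (list of
#'   character vectors), `n_kmers`, `n_unique`, `unique_fraction` (named
#'   numeric), `owner_of` (named character: unique k-mer -> owning node).
#' @export
index_graph <- function(graph, k = 31) {
  if (k < 3) stop("k must be >= 3")
  ids <- graph$nodes$id
  node_kmers <- lapply(graph$nodes$seq, function(s) {
    km <- seq_kmers(s, k)
    km <- km[!grepl("N", km, fixed = TRUE)]
    canonical_kmers(km)
  })
  names(node_kmers) <- ids
  if (all(lengths(node_kmers) == 0))
    stop("all nodes are shorter than k = ", k)
  # owners: number of distinct nodes containing each canonical kmer
  per_node_sets <- lapply(node_kmers, unique)
  all_kmers <- unlist(per_node_sets, use.names = FALSE)
  owner_node <- rep(ids, lengths(per_node_sets))
  n_owners <- table(all_kmers)
  uniq <- names(n_owners)[n_owners == 1]
  in_uniq <- all_kmers %in% uniq
  owner_of <- setNames(owner_node[in_uniq], all_kmers[in_uniq])
  n_kmers <- lengths(node_kmers)
  n_unique <- vapply(seq_along(ids), function(i) {
    km <- node_kmers[[i]]
    sum(km %in% uniq)
  }, numeric(1))
  unique_fraction <- ifelse(n_kmers > 0, n_unique / n_kmers, 0)
  structure(list(
    k = k, node_kmers = node_kmers,
    n_kmers = setNames(as.numeric(n_kmers), ids),
    n_unique = setNames(n_unique, ids),
    unique_fraction = setNames(unique_fraction, ids),
    owner_of = owner_of
  ), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d nodes, %d unique kmers\n",
              x$k, length(x$node_kmers), length(x$owner_of)))
  invisible(x)
}

#' Count unique-k-mer read hits per node
#'
#' Every canonical k-mer of every read that is owned by exactly one node
#' increments that node's count; k-mers owned by several nodes, or by
#' none, are ignored.
#'
#' @param index a `kmer_index`.
#' @param reads character vector of read sequences (possibly empty).
#' @return object of class `node_counts`: `counts` (named numeric),
#'   `total_reads`, `total_bases`.
#' @export
count_hits <- function(index, reads) {
  reads <- as.character(reads)
  k <- index$k
  ids <- names(index$node_kmers)
  counts <- setNames(numeric(length(ids)), ids)
  if (length(reads)) {
    kmers <- character(0)
    for (L in unique(nchar(reads))) {
      if (L < k) next
      grp <- reads[nchar(reads) == L]
      for (i in 1:(L - k + 1))
        kmers <- c(kmers, substring(grp, i, i + k - 1))
    }
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    if (length(kmers)) {
      owners <- index$owner_of[canonical_kmers(kmers)]
      tab <- table(owners[!is.na(owners)])
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  structure(list(counts = counts, total_reads = length(reads),
                 total_bases = sum(nchar(reads))),
            class = "node_counts")
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

#' Depth-normalize counts into copy-number estimates
#'
#' Per-node depth is `d(v) = counts(v) / n_unique(v)`, the observed hits
#' per expected unique k-mer position (equivalently, hits per k-mer
#' position divided by the unique fraction). The per-copy depth `D` is
#' the node-length-weighted median of `d(v)` over nodes with unique
#' fraction >= 0.5 and non-zero depth (robust to repeat-inflated nodes
#' and to the many zero-coverage nodes expected when the target genome
#' diverges from the pangenome). Each node's weight becomes `d(v) / D`;
#' nodes with unique fraction 0 get the -1 "unknown" sentinel.
#'
#' @param graph an `annotated_graph`.
#' @param counts a `node_counts` built from this graph.
#' @param index the `kmer_index` used for counting.
#' @return the graph with `weight` and `raw_count` filled in.
#' @export
estimate_copy_numbers <- function(graph, counts, index) {
  ids <- graph$nodes$id
  if (!setequal(names(counts$counts), names(index$unique_fraction)) ||
      !all(ids %in% names(counts$counts)))
    stop("counts/index do not match this graph")
  uf <- index$unique_fraction[ids]
  nu <- index$n_unique[ids]
  cn <- counts$counts[ids]
  d <- ifelse(nu > 0, cn / pmax(nu, 1), 0)
  eligible <- uf >= 0.5
  if (!any(eligible))
    stop("no node has unique_fraction >= 0.5; try a larger k")
  ref <- eligible & d > 0
  if (!any(ref))
    stop("no covered node with unique_fraction >= 0.5; ",
         "reads may not match the graph (or k is too large)")
  D <- weighted_median(d[ref], graph$nodes$length[ref])
  w <- ifelse(uf > 0, d / D, -1)
  graph$nodes$weight <- as.numeric(w)
  graph$nodes$raw_count <- as.integer(round(cn))
  graph
}

#' Annotate a graph with copy numbers from reads
#'
#' Convenience wrapper chaining [index_graph()], [count_hits()] and
#' [estimate_copy_numbers()].
#'
#' @param graph an `annotated_graph`.
#' @param reads character vector of read sequences.
#' @param k k-mer size (default 31).
#' @return the annotated graph.
#' @export
annotate_graph <- function(graph, reads, k = 31) {
  idx <- index_graph(graph, k)
  estimate_copy_numbers(graph, count_hits(idx, reads), idx)
}
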