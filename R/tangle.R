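# The three tangle-resolution problems as executable cost functions, a
# brute-force walk-enumeration oracle, and the prescriptive zero-copy
# baseline they are contrasted with.
#
# Plain:    C(W)  = sum_v (#W(v) - w(v))^2
# Oriented: C(W)  = sum_v (#W(v+) + #W(v-) - w(v))^2
# Diploid:  C(W1,W2) = sum_v (sum_i #Wi(v+) + #Wi(v-) - w(v))^2
# Numerically the oriented cost counts visits per base node, so one visit
# tabulation serves all variants; the variants differ in which walks are
# admissible (orientation use, one walk vs a pair).

check_variant <- function(variant) {
  if (!variant %in% c("plain", "oriented", "diploid"))
    stop("variant must be 'plain', 'oriented' or 'diploid'")
  variant
}

node_visits <- function(graph, walks) {
  visits <- setNames(numeric(nrow(graph$nodes)), graph$nodes$id)
  for (w in walks) {
    if (nrow(w) == 0) next
    tab <- table(w$node)
    visits[names(tab)] <- visits[names(tab)] + as.numeric(tab)
  }
  visits
}

cost_weights <- function(graph) {
  # the -1 "unknown" sentinel contributes as weight 0 to the cost
  pmax(graph$nodes$weight, 0)
}

#' Tangle-resolution cost of a single walk
#'
#' Sum over base nodes of the squared difference between the walk's visit
#' count (both orientations combined for the oriented variant) and the
#' node's estimated copy number.
#'
#' @param graph an `annotated_graph` with weights.
#' @param walk a `walk`, valid on `graph`.
#' @param variant `"plain"` or `"oriented"`; `"diploid"` is rejected
#'   (use [pair_cost()]).
#' @return non-negative numeric cost.
#' @export
walk_cost <- function(graph, walk, variant = "oriented") {
  check_variant(variant)
  if (variant == "diploid")
    stop("diploid cost takes a pair of walks; use pair_cost()")
  bad <- validate_walk(graph, walk)
  if (length(bad))
    stop("invalid walk: steps ", paste(bad, collapse = ", "),
         " do not traverse an edge")
  if (variant == "plain" && any(walk$orient == "-"))
    stop("plain variant walks must use '+' orientation only")
  sum((node_visits(graph, list(walk)) - cost_weights(graph))^2)
}

#' Tangle-resolution cost of a pair of walks (diploid)
#'
#' @param graph an `annotated_graph` with weights.
#' @param pair a `walk_pair` (or a list of two `walk`s).
#' @return non-negative numeric cost.
#' @export
pair_cost <- function(graph, pair) {
  if (inherits(pair, "walk_pair")) pair <- list(pair$first, pair$second)
  stopifnot(length(pair) == 2)
  for (i in 1:2) {
    bad <- validate_walk(graph, pair[[i]])
    if (length(bad))
      stop("invalid walk ", i, ": steps ", paste(bad, collapse = ", "),
           " do not traverse an edge")
  }
  sum((node_visits(graph, pair) - cost_weights(graph))^2)
}

# Oriented site labels and adjacency used by the oracle and the QUBO.
# Plain problems use "+" sites only.
graph_sites <- function(graph, variant) {
  ids <- graph$nodes$id
  if (variant == "plain") paste0(ids, "+")
  else as.vector(rbind(paste0(ids, "+"), paste0(ids, "-")))
}

site_adjacency <- function(graph, variant) {
  sites <- graph_sites(graph, variant)
  ed <- graph$edges
  from_site <- paste0(ed$from, ed$from_orient)
  to_site <- paste0(ed$to, ed$to_orient)
  keep <- from_site %in% sites & to_site %in% sites
  adj <- lapply(setNames(seq_along(sites), sites), function(i) integer(0))
  for (i in which(keep)) {
    f <- from_site[i]
    adj[[f]] <- c(adj[[f]], match(to_site[i], sites))
  }
  lapply(adj, function(v) sort(unique(v)))
}

site_to_walk <- function(sites) {
  if (length(sites) == 0) return(walk())
  n <- nchar(sites)
  walk(substr(sites, 1, n - 1), substr(sites, n, n))
}

# Enumerate all walks (as integer site-index vectors) of length 0..max_len.
# Lexicographic within each length; lengths ascending.
enumerate_walks <- function(adj, n_sites, max_len) {
  out <- list(integer(0))
  frontier <- list(integer(0))
  for (len in seq_len(max_len)) {
    nxt <- list()
    for (w in frontier) {
      succ <- if (length(w) == 0) seq_len(n_sites) else adj[[w[length(w)]]]
      for (s in succ) nxt[[length(nxt) + 1L]] <- c(w, s)
    }
    out <- c(out, nxt)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  out
}

walk_cost_by_sites <- function(site_node, weights, walk_idx) {
  visits <- tabulate(site_node[walk_idx], nbins = length(weights))
  sum((visits - weights)^2)
}

#' Exhaustive walk-enumeration oracle
#'
#' Enumerates every walk of length 0..`max_length` (for `"diploid"`, every
#' pair of walks of combined length at most `max_length`) and returns the
#' minimum tangle-resolution cost together with one optimal solution. Ties
#' are broken by shorter solutions first, then lexicographically on the
#' step list, so the output is deterministic. Intended as an independent
#' oracle for the QUBO route on small instances.
#'
#' @param graph an `annotated_graph` with weights.
#' @param variant `"plain"`, `"oriented"` or `"diploid"`.
#' @param max_length maximum walk length (combined length for diploid).
#' @return list with `cost` and `solution` (a `walk`, or a `walk_pair` for
#'   diploid).
#' @export
enumerate_optimum <- function(graph, variant = "oriented", max_length) {
  check_variant(variant)
  sites <- graph_sites(graph, variant)
  n_sites <- length(sites)
  bound <- (max(n_sites, 1))^max_length
  if (variant == "diploid") bound <- bound^2
  if (bound > 1e7)
    stop("search space too large: |V_or|^max_length = ", format(bound))
  adj <- site_adjacency(graph, variant)
  site_node <- match(sub("[+-]$", "", sites), graph$nodes$id)
  weights <- cost_weights(graph)
  walks <- enumerate_walks(adj, n_sites, max_length)

  if (variant != "diploid") {
    best <- NULL; best_cost <- Inf
    for (w in walks) {  # ascending length, lexicographic: first strict win
      cost <- walk_cost_by_sites(site_node, weights, w)
      if (cost < best_cost) { best_cost <- cost; best <- w }
    }
    return(list(cost = best_cost, solution = site_to_walk(sites[best])))
  }

  lens <- lengths(walks)
  best <- NULL; best_cost <- Inf
  for (i in seq_along(walks)) {
    li <- lens[i]
    if (li > max_length) next
    vi <- tabulate(site_node[walks[[i]]], nbins = length(weights))
    for (j in seq_along(walks)) {
      if (li + lens[j] > max_length) next
      vj <- tabulate(site_node[walks[[j]]], nbins = length(weights))
      cost <- sum((vi + vj - weights)^2)
      if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
    }
  }
  list(cost = best_cost,
       solution = walk_pair(site_to_walk(sites[walks[[best[1]]]]),
                            site_to_walk(sites[walks[[best[2]]]])))
}

#' Prescriptive zero-copy decomposition (baseline)
#'
#' The baseline behaviour contrasted with the cost-function approach:
#' nodes whose rounded weight is 0 are removed, and each maximal connected
#' run of the remaining nodes (connectivity through any oriented edge)
#' becomes one contig. Contigs are ordered by their smallest node id; a
#' contig that forms a simple path is reported in path order, otherwise
#' its nodes are sorted by id. All steps are reported with "+" orientation.
#'
#' @param graph an `annotated_graph` with weights.
#' @return list of `walk` objects (possibly empty).
#' @export
prescriptive_decompose <- function(graph) {
  w <- graph$nodes$weight
  keep <- graph$nodes$id[floor(pmax(w, 0) + 0.5) >= 1]
  if (length(keep) == 0) return(list())
  ed <- graph$edges
  ed <- ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
  # undirected base-node adjacency
  adj <- lapply(setNames(vector("list", length(keep)), keep), function(x) character(0))
  for (i in seq_len(nrow(ed))) {
    a <- ed$from[i]; b <- ed$to[i]
    if (a != b) {
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  seen <- setNames(rep(FALSE, length(keep)), keep)
  contigs <- list()
  for (start in sort(keep)) {
    if (seen[[start]]) next
    comp <- character(0); stack <- start
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      comp <- c(comp, v)
      stack <- c(stack, setdiff(adj[[v]], comp))
    }
    deg <- lengths(adj[comp])
    ordered <- sort(comp)
    if (length(comp) > 1 && all(deg <= 2) && sum(deg == 1) == 2) {
      # simple path: walk from the smaller endpoint
      ends <- sort(comp[deg == 1])
      path <- ends[1]; prev <- ""
      while (length(path) < length(comp)) {
        nbr <- setdiff(adj[[path[length(path)]]], prev)
        nbr <- intersect(nbr, comp)
        if (length(nbr) != 1) break
        prev <- path[length(path)]
        path <- c(path, nbr)
      }
      if (length(path) == length(comp)) ordered <- path
    }
    contigs[[length(contigs) + 1L]] <- walk(ordered, "+")
  }
  contigs
}
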