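# Time-indexed QUBO encoding of tangle resolution.
#
# Binary variable x[t, s, h] is 1 when haplotype h sits at site s at time t,
# where sites are the graph's (oriented) nodes plus a virtual "end" node
# with no sequence. The full cost is C1 + C2 + C3:
#   C1 = L1 * sum_t (sum_s x[t,s] - 1)^2        one site active per time
#   C2 = L2 * sum_t [ non-edge transitions + transitions leaving end ]
#   C3 = sum_v (sum_t visits of v - w(v))^2     fit to copy numbers
# Staying at end and entering end are free; only leaving end is penalized.
# Variable counts: (N+1)T plain, (2N+1)T oriented, 2(2N+1)T diploid.
# The instance stores C(x) = x' M x + offset with M symmetric; linear terms
# sit on the diagonal (x^2 = x for binary x).

#' Build a QUBO instance for a tangle-resolution problem
#'
#' @param graph an `annotated_graph` with weights.
#' @param variant `"plain"`, `"oriented"` or `"diploid"`.
#' @param alpha horizon factor; the walk-length horizon is
#'   `T = ceiling(alpha * sum(round(w)))` (minimum 1). Must exceed 1
#'   unless `T_override` is given. Default 1.2.
#' @param lambda1 penalty for the one-site-per-time constraint (default 10).
#' @param lambda2 penalty for non-edge transitions and for leaving the end
#'   node (default 5).
#' @param T_override explicit horizon, bypassing the `alpha` rule.
#' @return object of class `qubo_instance` with fields `n_vars`, `M`
#'   (dense symmetric matrix), `offset`, `var_map` (data frame: `idx`,
#'   `t`, `site`, `hap`), `T`, `lambda1`, `lambda2`, `alpha`, `variant`,
#'   `sites`, `graph_ref`.
#' @export
build_qubo <- function(graph, variant = "oriented", alpha = 1.2,
                       lambda1 = 10, lambda2 = 5, T_override = NULL) {
  check_variant(variant)
  w <- cost_weights(graph)
  names(w) <- graph$nodes$id
  if (is.null(T_override)) {
    if (alpha <= 1) stop("alpha must be > 1 (or give T_override)")
    sw <- sum(floor(w + 0.5))
    if (sw == 0)
      stop("sum of rounded weights is 0: give T_override for an empty problem")
    Tlen <- max(1L, as.integer(ceiling(alpha * sw)))
  } else {
    Tlen <- as.integer(T_override)
    if (Tlen < 1) stop("T_override must be >= 1")
  }

  gsites <- graph_sites(graph, variant)
  sites <- c(gsites, "end")
  n_sites <- length(sites)
  n_hap <- if (variant == "diploid") 2L else 1L
  n_vars <- n_hap * Tlen * n_sites

  var_map <- data.frame(
    idx = seq_len(n_vars),
    hap = rep(seq_len(n_hap), each = Tlen * n_sites),
    t = rep(rep(seq_len(Tlen), each = n_sites), times = n_hap),
    site = rep(sites, times = n_hap * Tlen),
    stringsAsFactors = FALSE
  )
  # vidx[site_pos, t, hap]
  vidx <- array(seq_len(n_vars), dim = c(n_sites, Tlen, n_hap))

  M <- matrix(0, n_vars, n_vars)
  offset <- 0
  add_pair <- function(i, j, c) {
    M[i, j] <<- M[i, j] + c / 2
    M[j, i] <<- M[j, i] + c / 2
  }

  adj <- site_adjacency(graph, variant)
  site_node <- match(sub("[+-]$", "", gsites), graph$nodes$id)
  end_pos <- n_sites

  for (h in seq_len(n_hap)) {
    # C1: one site per time
    for (t in seq_len(Tlen)) {
      vv <- vidx[, t, h]
      diag(M)[vv] <- diag(M)[vv] - lambda1
      for (a in seq_len(n_sites - 1))
        for (b in (a + 1):n_sites)
          add_pair(vv[a], vv[b], 2 * lambda1)
      offset <- offset + lambda1
    }
    # C2: transitions
    if (Tlen > 1) {
      allowed <- matrix(FALSE, n_sites, n_sites)
      for (s in seq_along(gsites)) allowed[s, adj[[s]]] <- TRUE
      allowed[, end_pos] <- TRUE        # entering end is free
      allowed[end_pos, end_pos] <- TRUE # staying at end is free
      # leaving end (end -> graph site) stays disallowed -> penalized
      for (t in seq_len(Tlen - 1)) {
        for (a in seq_len(n_sites))
          for (b in seq_len(n_sites))
            if (!allowed[a, b])
              add_pair(vidx[a, t, h], vidx[b, t + 1, h], lambda2)
      }
    }
  }

  # C3: per base node, all times, both orientations, all haplotypes
  for (v in seq_len(nrow(graph$nodes))) {
    group <- integer(0)
    for (h in seq_len(n_hap))
      for (s in which(site_node == v))
        group <- c(group, vidx[s, , h])
    wv <- unname(w[v])
    diag(M)[group] <- diag(M)[group] + (1 - 2 * wv)
    if (length(group) > 1) {
      for (a in seq_len(length(group) - 1))
        for (b in (a + 1):length(group))
          add_pair(group[a], group[b], 2)
    }
    offset <- offset + wv^2
  }

  structure(list(
    n_vars = n_vars, M = M, offset = offset, var_map = var_map,
    T = Tlen, lambda1 = lambda1, lambda2 = lambda2, alpha = alpha,
    variant = variant, sites = sites, n_hap = n_hap,
    graph_ref = paste(graph$nodes$id, collapse = ","), graph = graph
  ), class = "qubo_instance")
}

#' @export
print.qubo_instance <- function(x, ...) {
  cat(sprintf(
    "qubo_instance: %s, %d variables (T=%d, %d sites, %d haplotype(s))\n",
    x$variant, x$n_vars, x$T, length(x$sites), x$n_hap))
  invisible(x)
}

check_assignment <- function(instance, x) {
  x <- as.numeric(x)
  if (length(x) != instance$n_vars)
    stop("assignment length ", length(x), " does not match n_vars ",
         instance$n_vars)
  if (any(x != 0 & x != 1)) stop("assignment must be binary")
  x
}

#' Energy of a binary assignment
#'
#' @param instance a `qubo_instance`.
#' @param assignment binary vector of length `n_vars`.
#' @return `x' M x + offset`.
#' @export
qubo_energy <- function(instance, assignment) {
  x <- check_assignment(instance, assignment)
  as.numeric(crossprod(x, instance$M %*% x)) + instance$offset
}

#' Energies of all 2^n assignments
#'
#' Returns the full energy landscape, entry `b + 1` holding the energy of
#' the assignment whose bit `i` (1-based, little-endian) is bit `i - 1` of
#' the integer `b`. Built incrementally in O(n 2^n).
#'
#' @param instance a `qubo_instance`.
#' @param n_max refuse instances above this size (default 24).
#' @return numeric vector of length `2^n_vars`.
#' @export
qubo_energies <- function(instance, n_max = 24) {
  n <- instance$n_vars
  if (n > n_max) stop("n_vars = ", n, " exceeds the 2^n bound (", n_max, ")")
  M <- instance$M
  E <- instance$offset
  if (n == 0) return(E)
  # bit matrix over the first (k-1) variables, grown per variable
  B <- matrix(0, nrow = 1, ncol = 0)
  for (k in seq_len(n)) {
    if (k == 1) {
      delta <- M[1, 1]
    } else {
      delta <- M[k, k] + 2 * as.vector(B %*% M[seq_len(k - 1), k])
    }
    E <- c(E, E + delta)
    B <- rbind(cbind(B, 0), cbind(B, 1))
  }
  E
}

int_to_bits <- function(b, n) {
  # little-endian bits of integer(s) b (0-based), as 0/1 vector/matrix
  vapply(seq_len(n) - 1L, function(i) bitwAnd(b %/% 2^i, 1), numeric(length(b)))
}

#' Encode a walk (or pair) as a binary assignment
#'
#' Step `t` of the walk turns on its (site, t) variable; times beyond the
#' walk length sit at the end node.
#'
#' @param instance a `qubo_instance`.
#' @param walk a `walk` (plain/oriented) or `walk_pair` (diploid).
#' @return binary vector of length `n_vars`.
#' @export
encode_walk <- function(instance, walk) {
  walks <- if (inherits(walk, "walk_pair")) list(walk$first, walk$second)
           else list(walk)
  if (length(walks) != instance$n_hap)
    stop("expected ", instance$n_hap, " walk(s) for variant ",
         instance$variant)
  x <- numeric(instance$n_vars)
  n_sites <- length(instance$sites)
  for (h in seq_along(walks)) {
    wk <- walks[[h]]
    if (nrow(wk) > instance$T)
      stop("walk length ", nrow(wk), " exceeds horizon T = ", instance$T)
    step_sites <- if (nrow(wk) == 0) character(0)
                  else if (instance$variant == "plain") paste0(wk$node, "+")
                  else paste0(wk$node, wk$orient)
    pos <- match(step_sites, instance$sites)
    if (anyNA(pos)) stop("walk uses a site not in the instance")
    for (t in seq_len(instance$T)) {
      s <- if (t <= length(pos)) pos[t] else n_sites  # end
      x[((h - 1) * instance$T + (t - 1)) * n_sites + s] <- 1
    }
  }
  x
}

#' Decode a binary assignment into walks
#'
#' Total decoder for heuristic solver output. Per haplotype and time the
#' active site is the unique on-bit if there is exactly one, otherwise the
#' lowest-index on-bit (recorded as a `multi` diagnostic), or the end node
#' if none (`none` diagnostic). The site sequence is then split into
#' maximal valid sub-walks at end visits and at transitions that are not
#' graph edges (each split recorded as a `non_edge` diagnostic).
#'
#' @param instance a `qubo_instance`.
#' @param assignment binary vector of length `n_vars`.
#' @return list with `walks` (list over haplotypes, each a list of `walk`
#'   contigs ordered by start time) and `diagnostics` (data frame with
#'   columns `hap`, `t`, `type`).
#' @export
decode_assignment <- function(instance, assignment) {
  x <- check_assignment(instance, assignment)
  n_sites <- length(instance$sites)
  end_pos <- n_sites
  gr <- instance$graph
  ek <- graph_edge_keys(gr)
  diag_hap <- integer(0); diag_t <- integer(0); diag_type <- character(0)
  note <- function(h, t, type) {
    diag_hap <<- c(diag_hap, h); diag_t <<- c(diag_t, t)
    diag_type <<- c(diag_type, type)
  }
  hap_walks <- vector("list", instance$n_hap)
  for (h in seq_len(instance$n_hap)) {
    site_seq <- integer(instance$T)
    for (t in seq_len(instance$T)) {
      on <- which(x[((h - 1) * instance$T + (t - 1)) * n_sites +
                      seq_len(n_sites)] == 1)
      if (length(on) == 1) site_seq[t] <- on
      else if (length(on) == 0) { site_seq[t] <- end_pos; note(h, t, "none") }
      else { site_seq[t] <- on[1]; note(h, t, "multi") }
    }
    # split at end visits and non-edge transitions
    contigs <- list(); cur <- integer(0)
    for (t in seq_len(instance$T)) {
      s <- site_seq[t]
      if (s == end_pos) {
        if (length(cur)) { contigs[[length(contigs) + 1L]] <- cur; cur <- integer(0) }
        next
      }
      if (length(cur)) {
        prev <- instance$sites[cur[length(cur)]]
        this <- instance$sites[s]
        np <- nchar(prev); nt <- nchar(this)
        key <- edge_key(substr(prev, 1, np - 1), substr(prev, np, np),
                        substr(this, 1, nt - 1), substr(this, nt, nt))
        if (!key %in% ek) {
          note(h, t, "non_edge")
          contigs[[length(contigs) + 1L]] <- cur
          cur <- integer(0)
        }
      }
      cur <- c(cur, s)
    }
    if (length(cur)) contigs[[length(contigs) + 1L]] <- cur
    hap_walks[[h]] <- lapply(contigs, function(ix) site_to_walk(instance$sites[ix]))
  }
  list(
    walks = hap_walks,
    diagnostics = data.frame(hap = diag_hap, t = diag_t, type = diag_type,
                             stringsAsFactors = FALSE)
  )
}

#' Write a QUBO instance as sparse text
#'
#' Format: comment header lines `# key value` carrying `offset`, `T`,
#' `lambda1`, `lambda2`, `alpha`, `variant`, `n_vars`, followed by one
#' `i j coeff` triple per non-zero entry of the upper triangle (including
#' the diagonal), 1-based. The coefficient convention is
#' `C(x) = sum_{i<=j} c_ij x_i x_j + offset`.
#'
#' @param instance a `qubo_instance`.
#' @param path output file path.
#' @export
write_qubo <- function(instance, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(
    sprintf("# n_vars %d", instance$n_vars),
    sprintf("# offset %.17g", instance$offset),
    sprintf("# T %d", instance$T),
    sprintf("# lambda1 %.17g", instance$lambda1),
    sprintf("# lambda2 %.17g", instance$lambda2),
    sprintf("# alpha %.17g", instance$alpha),
    sprintf("# variant %s", instance$variant)
  ), con)
  M <- instance$M
  for (i in seq_len(instance$n_vars)) {
    for (j in i:instance$n_vars) {
      c_ij <- if (i == j) M[i, i] else 2 * M[i, j]
      if (c_ij != 0)
        writeLines(sprintf("%d %d %.17g", i, j, c_ij), con)
    }
  }
  invisible(path)
}

#' Read a sparse-text QUBO
#'
#' Inverse of [write_qubo()]. The variable map and source graph are not
#' recoverable from the file; the result supports energy evaluation and
#' solving but not decoding into walks.
#'
#' @param path input file path.
#' @return a `qubo_instance` (without `var_map`/`graph`).
#' @export
read_qubo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key, as = as.numeric) {
    m <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (!length(m)) stop("missing header '", key, "'")
    as(sub(paste0("^# ", key, " "), "", m[1]))
  }
  n <- as.integer(get_hdr("n_vars"))
  M <- matrix(0, n, n)
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, " +"))
    i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2])
    cc <- as.numeric(parts[, 3])
    for (r in seq_along(i)) {
      if (i[r] == j[r]) M[i[r], i[r]] <- M[i[r], i[r]] + cc[r]
      else {
        M[i[r], j[r]] <- M[i[r], j[r]] + cc[r] / 2
        M[j[r], i[r]] <- M[j[r], i[r]] + cc[r] / 2
      }
    }
  }
  structure(list(
    n_vars = n, M = M, offset = get_hdr("offset"),
    var_map = NULL, T = as.integer(get_hdr("T")),
    lambda1 = get_hdr("lambda1"), lambda2 = get_hdr("lambda2"),
    alpha = get_hdr("alpha"),
    variant = get_hdr("variant", as = identity),
    sites = NULL, n_hap = if (get_hdr("variant", identity) == "diploid") 2L else 1L,
    graph_ref = NA_character_, graph = NULL
  ), class = "qubo_instance")
}
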