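# Turning decoded walks into sequence and scoring candidate assemblies
# against a known truth.
#
# Alignment is by unique-k-mer anchors: k-mers occurring exactly once in
# the truth and exactly once in a contig (either strand) pair up as
# anchors, the longest strand-consistent co-linear chain (monotone on both
# axes, gaps capped at 500 bp) forms an alignment block, and the
# inter-anchor gaps are filled by pairwise alignment to obtain match,
# mismatch and indel counts. This replaces a general-purpose read mapper:
# on the small synthetic genomes evaluated here, exact unique anchors are
# dense and the procedure is deterministic.

#' Spell out the sequence of a walk
#'
#' Concatenates node sequences in walk order, reverse-complementing
#' steps with "-" orientation.
#'
#' @param graph an `annotated_graph`.
#' @param walk a valid `walk`.
#' @return DNA string (empty string for the empty walk).
#' @export
walk_to_sequence <- function(graph, walk) {
  bad <- validate_walk(graph, walk)
  if (length(bad))
    stop("invalid walk: steps ", paste(bad, collapse = ", "),
         " do not traverse an edge")
  if (nrow(walk) == 0) return("")
  seqs <- graph$nodes$seq[match(walk$node, graph$nodes$id)]
  neg <- walk$orient == "-"
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  paste(seqs, collapse = "")
}

# positions (0-based) of each k-mer occurring exactly once in seq
unique_kmer_positions <- function(seq, k) {
  km <- seq_kmers(seq, k)
  if (length(km) == 0)
    return(data.frame(kmer = character(0), pos = integer(0)))
  keep <- !(km %in% km[duplicated(km)])
  data.frame(kmer = km[keep], pos = which(keep) - 1L,
             stringsAsFactors = FALSE)
}

# longest co-linear chain of anchors (cpos, tpos both strictly increasing,
# gap <= max_gap on both axes); anchors assumed sorted by cpos
chain_anchors <- function(cpos, tpos, k, max_gap) {
  n <- length(cpos)
  if (n == 0) return(integer(0))
  score <- rep(1L, n); back <- rep(0L, n)
  for (i in seq_len(n)) {
    lo <- which(cpos < cpos[i] & tpos < tpos[i] &
                  cpos[i] - cpos < max_gap + k &
                  tpos[i] - tpos < max_gap + k)
    if (length(lo)) {
      j <- lo[which.max(score[lo])]
      score[i] <- score[j] + 1L
      back[i] <- j
    }
  }
  i <- which.max(score)
  chain <- integer(0)
  while (i != 0) { chain <- c(i, chain); i <- back[i] }
  chain
}

# align two gap substrings; returns counts and truth-coordinate mismatch
# positions (0-based, relative to tstart)
align_gap <- function(cseq, tseq) {
  nc <- nchar(cseq); nt <- nchar(tseq)
  if (nc == 0 && nt == 0)
    return(list(match = 0, mismatch = 0, ins = 0, del = 0,
                indel_events = integer(0), mm_t = integer(0)))
  if (nc == 0)
    return(list(match = 0, mismatch = 0, ins = 0, del = nt,
                indel_events = nt, mm_t = integer(0)))
  if (nt == 0)
    return(list(match = 0, mismatch = 0, ins = nc, del = 0,
                indel_events = nc, mm_t = integer(0)))
  # stiff gap costs: between exact anchors, length differences are real
  # indels, while equal-length divergence should align column-on-column
  # as substitutions rather than as spurious gap pairs
  aln <- Biostrings::pairwiseAlignment(
    cseq, tseq, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 10, gapExtension = 10
  )
  # pattern = contig, subject = truth: insertion() = extra contig bases
  # (gaps in truth), deletion() = missing contig bases (gaps in contig)
  ins_w <- unlist(IRanges::width(Biostrings::insertion(aln)))
  del_w <- unlist(IRanges::width(Biostrings::deletion(aln)))
  mm <- Biostrings::mismatchTable(aln)
  mm_t <- if (nrow(mm)) mm$SubjectStart - 1L else integer(0)
  list(
    match = Biostrings::nmatch(aln),
    mismatch = Biostrings::nmismatch(aln),
    ins = sum(ins_w), del = sum(del_w),
    indel_events = c(ins_w, del_w),
    mm_t = mm_t
  )
}

# blocks for one contig strand; cseq is the (possibly reverse-complemented)
# contig sequence whose coordinates are native to the anchors
strand_blocks <- function(cseq, truth_uk, truth, anchor_k, max_gap,
                          min_anchors) {
  cu <- unique_kmer_positions(cseq, anchor_k)
  m <- match(cu$kmer, truth_uk$kmer)
  hit <- !is.na(m)
  anchors <- data.frame(cpos = cu$pos[hit], tpos = truth_uk$pos[m[hit]])
  anchors <- anchors[order(anchors$cpos, anchors$tpos), , drop = FALSE]
  blocks <- list()
  while (nrow(anchors) >= min_anchors) {
    ch <- chain_anchors(anchors$cpos, anchors$tpos, anchor_k, max_gap)
    if (length(ch) < min_anchors) break
    a <- anchors[ch, , drop = FALSE]
    # merge into exact runs: consecutive anchors with equal offset within k
    off_same <- diff(a$cpos) == diff(a$tpos) & diff(a$cpos) <= anchor_k
    run_id <- cumsum(c(1, !off_same))
    run_groups <- split(seq_len(nrow(a)), factor(run_id, levels = unique(run_id)))
    runs <- do.call(rbind, lapply(run_groups, function(ix)
      data.frame(cs = a$cpos[ix[1]], ts = a$tpos[ix[1]],
                 ce = a$cpos[ix[length(ix)]] + anchor_k,
                 te = a$tpos[ix[length(ix)]] + anchor_k)))
    match_n <- sum(runs$ce - runs$cs)
    mism <- 0; ins <- 0; del <- 0
    indel_events <- integer(0); mm_t <- integer(0)
    if (nrow(runs) > 1) {
      for (r in seq_len(nrow(runs) - 1)) {
        gp <- align_gap(
          substr_safe(cseq, runs$ce[r] + 1, runs$cs[r + 1]),
          substr_safe(truth, runs$te[r] + 1, runs$ts[r + 1])
        )
        match_n <- match_n + gp$match; mism <- mism + gp$mismatch
        ins <- ins + gp$ins; del <- del + gp$del
        indel_events <- c(indel_events, gp$indel_events)
        mm_t <- c(mm_t, gp$mm_t + runs$te[r])
      }
    }
    blocks[[length(blocks) + 1L]] <- list(
      cstart = runs$cs[1], cend = runs$ce[nrow(runs)],
      tstart = runs$ts[1], tend = runs$te[nrow(runs)],
      match = match_n, mismatch = mism, ins = ins, del = del,
      indel_ge10 = sum(indel_events >= 10), mm_t = mm_t
    )
    # best chain claims its contig span; drop its anchors and any others inside
    span <- c(runs$cs[1], runs$ce[nrow(runs)])
    anchors <- anchors[anchors$cpos + anchor_k <= span[1] |
                         anchors$cpos >= span[2], , drop = FALSE]
  }
  blocks
}

substr_safe <- function(x, start, stop) {
  if (stop < start) "" else substr(x, start, stop)
}

#' Align candidate contigs to the truth by unique-anchor chaining
#'
#' @param candidate_contigs character vector of contig sequences.
#' @param truth non-empty truth DNA string.
#' @param anchor_k anchor k-mer size (default 21).
#' @param max_gap maximum gap between chained anchors on either axis
#'   (default 500).
#' @param min_anchors minimum anchors per block (default 2).
#' @return data frame of alignment blocks: `contig_id`, `contig_start`,
#'   `contig_end`, `truth_start`, `truth_end` (0-based half-open),
#'   `strand`, `n_matches`, `n_mismatches`, `n_ins`, `n_del`,
#'   `indel_ge10` (gap events of >= 10 bases), and a list column
#'   `mismatch_tpos` of truth-coordinate mismatch positions. Sorted by
#'   contig then contig_start; empty when no anchors exist.
#' @export
align_blocks <- function(candidate_contigs, truth, anchor_k = 21,
                         max_gap = 500, min_anchors = 2) {
  if (nchar(truth) == 0) stop("truth must be non-empty")
  tu <- unique_kmer_positions(truth, anchor_k)
  rows <- list()
  for (ci in seq_along(candidate_contigs)) {
    cseq <- candidate_contigs[ci]
    Lc <- nchar(cseq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cseq else revcomp(cseq)
      for (b in strand_blocks(s, tu, truth, anchor_k, max_gap, min_anchors)) {
        cs <- b$cstart; ce <- b$cend
        if (strand == "-") { tmp <- cs; cs <- Lc - ce; ce <- Lc - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = ci, contig_start = cs, contig_end = ce,
          truth_start = b$tstart, truth_end = b$tend, strand = strand,
          n_matches = b$match, n_mismatches = b$mismatch,
          n_ins = b$ins, n_del = b$del, indel_ge10 = b$indel_ge10,
          stringsAsFactors = FALSE
        )
        rows[[length(rows)]]$mismatch_tpos <- list(b$mm_t)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = integer(0), contig_start = integer(0),
                      contig_end = integer(0), truth_start = integer(0),
                      truth_end = integer(0), strand = character(0),
                      n_matches = integer(0), n_mismatches = integer(0),
                      n_ins = integer(0), n_del = integer(0),
                      indel_ge10 = integer(0)))
  out <- do.call(rbind, rows)
  out <- resolve_overlaps(out)
  out[order(out$contig_id, out$contig_start), , drop = FALSE]
}

# each contig region belongs to at most one block: keep the block with more
# matches when two blocks of the same contig overlap (secondary filtering)
resolve_overlaps <- function(blocks) {
  keep <- rep(TRUE, nrow(blocks))
  o <- order(-blocks$n_matches)
  for (ii in seq_along(o)) {
    i <- o[ii]
    if (!keep[i]) next
    for (jj in seq_along(o)) {
      j <- o[jj]
      if (i == j || !keep[j] || blocks$n_matches[j] > blocks$n_matches[i]) next
      if (blocks$contig_id[i] == blocks$contig_id[j] &&
          blocks$contig_start[i] < blocks$contig_end[j] &&
          blocks$contig_start[j] < blocks$contig_end[i] && j != i)
        if (blocks$n_matches[j] < blocks$n_matches[i] ||
            (blocks$n_matches[j] == blocks$n_matches[i] && jj > ii))
          keep[j] <- FALSE
    }
  }
  blocks[keep, , drop = FALSE]
}

interval_union_width <- function(starts, ends) {
  if (length(starts) == 0) return(0)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > cur_e) {
      total <- total + cur_e - cur_s
      cur_s <- starts[i]; cur_e <- ends[i]
    } else cur_e <- max(cur_e, ends[i])
  }
  total + cur_e - cur_s
}

#' N50 of a set of contig lengths
#'
#' Largest length L such that contigs of length >= L together cover at
#' least half the total assembly.
#'
#' @param lengths numeric vector of contig lengths.
#' @return numeric N50 (0 for an empty assembly).
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0 || sum(lengths) == 0) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Score an assembly against the truth
#'
#' Computes the eight evaluation metrics: `covered_pct` (union of truth
#' intervals covered by blocks, as % of truth length), `used_pct` (union
#' of contig intervals, as % of total contig length), `n_contigs`, `n50`,
#' `breaks` (per contig, one less than its number of blocks, summed —
#' false-join discontinuities), `indels_ge10` (within-block gap events of
#' >= 10 bases), `diff_regions` (fixed, non-overlapping 100-base truth
#' windows containing >= 30 mismatching aligned bases), and
#' `identity_pct` (matches over aligned columns, all blocks).
#'
#' @param blocks data frame from [align_blocks()].
#' @param candidate_contigs the contig sequences the blocks came from.
#' @param truth the truth sequence.
#' @return named list of class `evaluation_report`.
#' @export
evaluate_assembly <- function(blocks, candidate_contigs, truth) {
  Lt <- nchar(truth)
  Lc_total <- sum(nchar(candidate_contigs))
  covered <- interval_union_width(blocks$truth_start, blocks$truth_end)
  used <- interval_union_width(
    blocks$contig_start + (blocks$contig_id - 1) * (Lc_total + 1),
    blocks$contig_end + (blocks$contig_id - 1) * (Lc_total + 1))
  breaks <- 0
  if (nrow(blocks))
    breaks <- sum(pmax(0, table(blocks$contig_id) - 1))
  mm_pos <- if (nrow(blocks) && !is.null(blocks$mismatch_tpos))
    unlist(blocks$mismatch_tpos) else integer(0)
  diff_regions <- if (length(mm_pos))
    sum(table(mm_pos %/% 100) >= 30) else 0
  cols <- sum(blocks$n_matches) + sum(blocks$n_mismatches) +
    sum(blocks$n_ins) + sum(blocks$n_del)
  structure(list(
    covered_pct = 100 * covered / Lt,
    used_pct = if (Lc_total > 0) 100 * used / Lc_total else 0,
    n_contigs = length(candidate_contigs),
    n50 = n50(nchar(candidate_contigs)),
    breaks = breaks,
    indels_ge10 = sum(blocks$indel_ge10),
    diff_regions = diff_regions,
    identity_pct = if (cols > 0) 100 * sum(blocks$n_matches) / cols else 0
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    paste0("%%Covered %.1f  %%Used %.1f  Contigs %d  Breaks %d  ",
           "Indel %d  No.Diff %d  N50 %d  %%Identity %.1f\n"),
    x$covered_pct, x$used_pct, x$n_contigs, x$breaks,
    x$indels_ge10, x$diff_regions, x$n50, x$identity_pct))
  invisible(x)
}

#' One-line TSV of an evaluation report
#'
#' Column order: %Covered, %Used, Contigs, Breaks, Indel, No.Diff, N50,
#' %Identity.
#'
#' @param report an `evaluation_report`.
#' @return single TSV string (no header).
#' @export
report_tsv <- function(report) {
  sprintf("%.1f\t%.1f\t%d\t%d\t%d\t%d\t%d\t%.1f",
          report$covered_pct, report$used_pct, report$n_contigs,
          report$breaks, report$indels_ge10, report$diff_regions,
          as.integer(report$n50), report$identity_pct)
}

#' Polish a candidate sequence by read consensus
#'
#' Reads are placed on the candidate by unique-anchor voting (each read
#' k-mer matching a candidate-unique k-mer votes for an offset and
#' strand; the majority placement wins), then each candidate column with
#' at least `min_cov` covering reads is replaced by the majority base.
#' Substitutions only — no indel edits. Deterministic; ties keep the
#' existing base.
#'
#' @param candidate DNA string.
#' @param reads character vector of read sequences.
#' @param anchor_k placement k-mer size (default 21).
#' @param min_cov minimum covering reads to touch a column (default 3).
#' @return polished DNA string.
#' @export
consensus_polish <- function(candidate, reads, anchor_k = 21, min_cov = 3) {
  L <- nchar(candidate)
  if (length(reads) == 0 || L < anchor_k) return(candidate)
  cu <- unique_kmer_positions(candidate, anchor_k)
  lookup <- setNames(cu$pos, cu$kmer)
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, nrow = 4, ncol = L, dimnames = list(bases, NULL))
  cover <- integer(L)
  for (rd in reads) {
    for (s in c("+", "-")) {
      sq <- if (s == "+") rd else revcomp(rd)
      km <- seq_kmers(sq, anchor_k)
      hit <- match(km, names(lookup))
      ok <- which(!is.na(hit))
      if (!length(ok)) next
      offs <- unname(lookup[hit[ok]]) - (ok - 1L)  # candidate pos of read start
      off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
      pos <- off + seq_len(nchar(sq))  # 1-based candidate columns
      inb <- pos >= 1 & pos <= L
      if (!any(inb)) break
      b <- strsplit(sq, "")[[1]][inb]
      p <- pos[inb]
      known <- b %in% bases
      bi <- match(b[known], bases)
      pk <- p[known]
      # positions within one read are distinct, so this is collision-free
      idx <- cbind(bi, pk)
      votes[idx] <- votes[idx] + 1L
      cover[pk] <- cover[pk] + 1L
      break  # placed on this strand; don't place again
    }
  }
  out <- strsplit(candidate, "")[[1]]
  fix <- which(cover >= min_cov)
  for (p in fix) {
    v <- votes[, p]
    top <- bases[which(v == max(v))]
    if (length(top) == 1 && top != out[p] && max(v) > v[match(out[p], bases)])
      out[p] <- top
  }
  paste(out, collapse = "")
}

#' Assemble, decode and evaluate one instance end to end
#'
#' Runs the QUBO route on an annotated graph: build the instance, solve
#' with tabu search, decode into contigs, spell their sequences, align
#' against the truth and score.
#'
#' @param graph an `annotated_graph` with weights.
#' @param truth truth DNA string.
#' @param variant problem variant (default "oriented").
#' @param seed RNG seed for the solver.
#' @param ... passed to [build_qubo()].
#' @return list with `report`, `contigs` (sequences), `walks`, `result`.
#' @export
assemble_evaluate <- function(graph, truth, variant = "oriented", seed = 1,
                              ...) {
  inst <- build_qubo(graph, variant = variant, ...)
  sol <- solve_and_decode(inst, method = "tabu", seed = seed)
  wks <- unlist(sol$decoded$walks, recursive = FALSE)
  contigs <- vapply(wks, function(w) walk_to_sequence(graph, w), character(1))
  contigs <- contigs[nchar(contigs) > 0]
  blocks <- align_blocks(contigs, truth)
  list(report = evaluate_assembly(blocks, contigs, truth),
       contigs = contigs, walks = wks, result = sol$result)
}
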