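# Small sequence helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  nz <- nchar(x) > 0
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Random DNA string
#'
#' Draws bases i.i.d. uniformly from A, C, G, T using the current RNG state.
#'
#' @param n length in bases.
#' @return a single character string.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All k-length windows of a single sequence (character vector, possibly empty).
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1), k:L)
}

# Canonical form: lexicographic min of a kmer and its reverse complement.
# A < C < G < T holds in any locale for these letters.
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path input file; format picked from the extension
#'   (`.fq`/`.fastq`, optionally gzipped, is read as FASTQ).
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ with a constant quality
#'
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @param qual constant Phred quality character (default "I", Q40).
#' @export
write_fastq <- function(reads, path, qual = "I") {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(
    nchar(reads), function(n) strrep(qual, n), character(1)
  ))
  qs <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(q)
  )
  Biostrings::writeQualityScaledXStringSet(qs, filepath = path)
  invisible(path)
}
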